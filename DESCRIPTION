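Package: koopkernel
Title: Kernel-Based Spectral Approximation of Koopman Generators and
    Schrodinger Operators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Approximates second-order differential operators -- Koopman
    generators of drift-diffusion processes, general elliptic operators, and
    Schrodinger operators -- from scattered data using derivative-reproducing
    kernels. Eigenvalues and eigenfunctions are obtained from Gram-matrix
    generalized eigenvalue problems whose size is the number of samples, with
    a reversible-dynamics variant that needs only an equilibrated trajectory.
    Includes pipelines for metastable-state analysis of molecular-dynamics-like
    trajectories, quantum eigenstate computation (directly and through the
    duality between Schrodinger operators and stochastic processes), and
    operator-based spectral embedding of manifold data, together with built-in
    benchmark systems, an Euler-Maruyama simulator, and point-cloud samplers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
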