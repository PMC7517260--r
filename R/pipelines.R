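# End-to-end analyses: metastable decomposition of trajectories, quantum
# eigenstates (direct and via the stochastic-process duality), and
# operator-spectral manifold embedding.

#' Metastable decomposition of an equilibrated trajectory
#'
#' Runs the reversible (symmetric) kernel estimator of the negative generator
#' on equilibrated trajectory data -- only `G0`, the gradient Gram matrices
#' and the (constant) diffusion are needed, no drift estimates -- and clusters
#' the samples into metastable sets with seeded k-means on the values of the
#' dominant eigenfunctions. The number of dominant modes is detected by the
#' spectral-gap rule of [spectral_gap_index()] unless `n_sets` is given.
#' The caller is responsible for the trajectory being equilibrated.
#'
#' @param data A `koop_trajectory` (carrying its diffusion as an attribute) or
#'   any point container plus an explicit `sigma`.
#' @param kernel A `koop_kernel`; default Gaussian with bandwidth 0.5.
#' @param n_eig Number of eigenpairs to estimate (default 10).
#' @param n_sets Number of metastable sets; default: detected from the gap.
#' @param sigma Diffusion (constant matrix/scalar), overriding the trajectory
#'   attribute.
#' @param epsilon,rank_tol Solver regularization (see [solve_symmetric()]).
#' @param seed Seed for k-means (default 1; `nstart = 25` restarts make the
#'   labels stable across seeds up to permutation).
#' @return A `koop_metastable` with the spectrum, cluster `labels`,
#'   `n_sets`, the detected number of dominant modes `n_dominant`, and an
#'   `assignments` tibble (points, eigenfunction values, cluster).
#' @export
metastable_analysis <- function(data, kernel = NULL, n_eig = 10, n_sets = NULL,
                                sigma = NULL, epsilon = NULL,
                                rank_tol = 1e-10, seed = 1) {
  x <- as_points(data)
  kernel <- kernel %||% gaussian_kernel(0.5, ncol(x))
  sigma <- sigma %||% attr(data, "sigma")
  if (is.null(sigma)) {
    stop_config("no diffusion available: pass `sigma` or a trajectory carrying one.")
  }
  if (!is.null(n_sets) && n_sets > n_eig) {
    stop_config("`n_sets` cannot exceed `n_eig`.")
  }
  g0 <- assemble_g0(x, kernel)
  g1 <- assemble_g1(x, kernel, sigma)
  spec <- solve_symmetric(g1, g0, epsilon = epsilon, n_eig = n_eig,
                          rank_tol = rank_tol, points = x, kernel = kernel)
  n_dom <- spectral_gap_index(Re(spec$values))
  k <- n_sets %||% n_dom
  phi <- Re(g0 %*% spec$coefficients[, seq_len(k), drop = FALSE])
  km <- with_seed(seed, stats::kmeans(phi, centers = k, nstart = 25,
                                      iter.max = 100))
  assignments <- tibble::as_tibble(as.data.frame(x)) |>
    stats::setNames(paste0("x", seq_len(ncol(x))))
  for (j in seq_len(k)) assignments[[paste0("phi", j)]] <- phi[, j]
  assignments$cluster <- factor(km$cluster)
  structure(list(spectrum = spec, labels = km$cluster, n_sets = k,
                 n_dominant = n_dom, assignments = assignments, seed = seed),
            class = "koop_metastable")
}

#' @export
print.koop_metastable <- function(x, ...) {
  cat(sprintf("<koop_metastable> %d dominant modes detected, %d sets, %d samples\n",
              x$n_dominant, x$n_sets, nrow(x$assignments)))
  cat("  eigenvalues of -L:",
      paste(sprintf("%.4g", utils::head(Re(x$spectrum$values), 6)),
            collapse = ", "), "...\n")
  invisible(x)
}

#' Detect the number of dominant eigenvalues
#'
#' For an ascending spectrum of \eqn{-L}, the near-zero stationary eigenvalue
#' always counts as dominant; among the remaining leading eigenvalues the gap
#' is placed at the largest ratio of consecutive values (each floored at
#' `floor` to avoid division blow-up), and the dominant count is the number of
#' eigenvalues before that jump.
#'
#' @param values Ascending eigenvalues of `-L` (real parts used).
#' @param n_max Number of leading eigenvalues scanned (default 10).
#' @param floor Lower clamp for denominators (default `1e-3`).
#' @return Integer count of dominant eigenvalues (at least 1).
#' @export
spectral_gap_index <- function(values, n_max = 10, floor = 1e-3) {
  v <- Re(values)[seq_len(min(n_max, length(values)))]
  if (length(v) < 3) return(length(v))
  # start the ratio scan at the second eigenvalue: lambda_0 ~ 0 is always
  # present for an ergodic system and would dominate every true gap
  ratios <- vapply(2:(length(v) - 1), function(l) {
    v[l + 1] / max(v[l], floor)
  }, numeric(1))
  which.max(ratios) + 1L
}

#' Quantum eigenstates by direct operator estimation
#'
#' Assembles `G2` and `G0` for the Hamiltonian
#' \eqn{H = -\frac{\hbar^2}{2m}\Delta + W} on scattered points and solves the
#' general eigenvalue problem; energies come out ascending (ground state
#' first). Samples at which the potential is singular or non-finite are
#' rejected with a warning.
#'
#' @param data Points (matrix, tibble, or sampler output).
#' @param model A `koop_schrodinger`.
#' @param kernel A `koop_kernel`; default Gaussian with bandwidth 1.
#' @param n_eig Number of energy levels (default 10).
#' @param epsilon,rank_tol Solver regularization (see [solve_general()]).
#' @return A `koop_spectrum` (`operator = "schrodinger"`); `values` are the
#'   energies, eigenfunctions via [evaluate_eigenfunctions()].
#' @export
schrodinger_direct <- function(data, model, kernel = NULL, n_eig = 10,
                               epsilon = NULL, rank_tol = 1e-10) {
  stopifnot(inherits(model, "koop_schrodinger"))
  x <- as_points(data, model$d)
  w <- schrodinger_potential_at(model, x)
  bad <- !is.finite(w)
  if (model$singular_radius > 0) {
    bad <- bad | sqrt(rowSums(x^2)) < model$singular_radius
  }
  if (any(bad)) {
    warning(sprintf("%d sample(s) rejected at potential singularities.",
                    sum(bad)))
    x <- x[!bad, , drop = FALSE]; w <- w[!bad]
  }
  kernel <- kernel %||% gaussian_kernel(1, model$d)
  coeffs <- coefficient_samples(x, a = model$hbar^2 / model$mass, w = w)
  g0 <- assemble_g0(x, kernel)
  g2 <- assemble_g2(x, kernel, coeffs)
  solve_general(g2, g0, epsilon = epsilon, n_eig = n_eig,
                operator = "schrodinger", rank_tol = rank_tol,
                points = x, kernel = kernel)
}

#' Quantum eigenstates through the drift-diffusion duality
#'
#' Builds the Langevin process whose Koopman generator is unitarily
#' equivalent to the Hamiltonian (via the ground state,
#' [sde_from_ground_state()]), estimates the generator spectrum with the
#' general kernel estimator (`c1 = -b`, `W = 0`), and maps eigenvalues back to
#' energies \eqn{E_\ell = E_0 - \lambda_\ell} and eigenfunctions to
#' wavefunctions \eqn{\psi_\ell = \psi_0\varphi_\ell}.
#'
#' @param gs A [ground_state()].
#' @param data Training data: a point container (e.g. ball samples) or a
#'   trajectory of the dual process.
#' @param kernel A `koop_kernel`; default Gaussian with bandwidth 1.
#' @param hbar,mass Physical constants.
#' @param n_eig Number of levels.
#' @param epsilon,rank_tol Solver regularization.
#' @return A `koop_wavefunctions` (energies + wavefunction evaluators).
#' @export
schrodinger_via_sde <- function(gs, data, kernel = NULL, hbar = 1, mass = 1,
                                n_eig = 10, epsilon = NULL, rank_tol = 1e-10) {
  stopifnot(inherits(gs, "koop_ground_state"))
  x <- as_points(data, gs$d)
  model <- sde_from_ground_state(gs, hbar = hbar, mass = mass)
  kernel <- kernel %||% gaussian_kernel(1, gs$d)
  coeffs <- operator_coefficients(model, x, operator = "generator")
  g0 <- assemble_g0(x, kernel)
  g2 <- assemble_g2(x, kernel, coeffs)
  spec <- solve_general(g2, g0, epsilon = epsilon, n_eig = n_eig,
                        operator = "generator", rank_tol = rank_tol,
                        points = x, kernel = kernel)
  spectrum_transform(spec, gs)
}

#' Gaussian kernel density estimate
#'
#' Fits \eqn{\hat\rho(x) = \frac{1}{M(2\pi\varsigma^2)^{d/2}}
#' \sum_m e^{-\|x - x_m\|^2/2\varsigma^2}} and exposes the associated
#' potential \eqn{U = -\log\hat\rho} through its gradient, which is free of
#' the normalization constant. Evaluation is done in the log domain with a
#' max-shift so the estimate never underflows to zero.
#'
#' @param data Training points.
#' @param bandwidth KDE bandwidth \eqn{\varsigma_{kde}} (positive).
#' @return A `koop_kde` object.
#' @export
kde_fit <- function(data, bandwidth) {
  if (!is.numeric(bandwidth) || bandwidth <= 0) {
    stop_config("`bandwidth` must be positive.")
  }
  x <- as_points(data)
  structure(list(points = x, bandwidth = bandwidth, d = ncol(x)),
            class = "koop_kde")
}

#' @export
print.koop_kde <- function(x, ...) {
  cat(sprintf("<koop_kde> %d points in R^%d, bandwidth %g\n",
              nrow(x$points), x$d, x$bandwidth))
  invisible(x)
}

#' Kernel density values
#'
#' @param model A `koop_kde`.
#' @param newdata Query points.
#' @param log Return log-density (default FALSE).
#' @return Vector of (log-)density values; strictly positive by construction.
#' @export
kde_density <- function(model, newdata, log = FALSE) {
  stopifnot(inherits(model, "koop_kde"))
  q <- as_points(newdata, model$d)
  s2 <- model$bandwidth^2
  d2 <- pairwise_sqdist(q, model$points)
  expo <- -d2 / (2 * s2)
  shift <- apply(expo, 1, max)
  lse <- shift + base::log(rowSums(exp(expo - shift)))
  ld <- lse - base::log(nrow(model$points)) -
    model$d / 2 * base::log(2 * pi * s2)
  if (log) ld else exp(ld)
}

#' Gradient of the KDE potential U = -log density
#'
#' \eqn{\nabla U(x) = \frac{1}{\varsigma^2}\,
#' \frac{\sum_m (x - x_m)\,k(x, x_m)}{\sum_m k(x, x_m)}}; normalization
#' constants cancel, so the result is invariant to rescaling the density.
#'
#' @param model A `koop_kde`.
#' @param newdata Query points (`R x d`).
#' @return `R x d` matrix of gradients.
#' @export
kde_grad_logdensity <- function(model, newdata) {
  stopifnot(inherits(model, "koop_kde"))
  q <- as_points(newdata, model$d)
  s2 <- model$bandwidth^2
  d2 <- pairwise_sqdist(q, model$points)
  expo <- -d2 / (2 * s2)
  shift <- apply(expo, 1, max)
  wk <- exp(expo - shift)        # row-rescaled weights; scale cancels below
  den <- rowSums(wk)
  out <- matrix(0, nrow(q), model$d)
  for (i in seq_len(model$d)) {
    diffi <- outer(q[, i], model$points[, i], "-")
    out[, i] <- rowSums(wk * diffi) / (s2 * den)
  }
  out
}

#' Operator-spectral manifold embedding
#'
#' Embeds a point cloud by the leading nontrivial eigenfunctions of an
#' estimated Kolmogorov backward operator whose invariant measure is the
#' sampling density (the alpha = 1/2 anisotropic-diffusion-map operator
#' \eqn{L f = -\nabla U\cdot\nabla f + \Delta f} with \eqn{U = -\log\rho}).
#' Two estimators are available:
#'
#' * `"reversible"` (default): the symmetric estimator with \eqn{\sigma =
#'   \sqrt{2} I}, which targets exactly this operator with the sampling
#'   measure as invariant measure and needs no density estimate at all.
#' * `"kde_drift"`: the general estimator with drift \eqn{b = -\nabla U} taken
#'   from a Gaussian KDE ([kde_fit()]), i.e. the operator assembled from
#'   explicit coefficients. Appropriate when the data have full-dimensional
#'   support and the KDE bandwidth resolves the sampling density.
#'
#' The leading near-constant eigenfunction is dropped; the next `n_coords`
#' eigenfunction values at the data points are the embedding coordinates.
#'
#' @param data Point cloud (matrix or tibble; latent columns are ignored).
#' @param kernel Operator kernel; default Gaussian with bandwidth
#'   `0.75 * median nearest-neighbour distance` (small enough to separate
#'   nearby manifold sheets, large enough to overlap neighbouring samples).
#' @param n_coords Number of embedding coordinates (default 2).
#' @param method `"reversible"` or `"kde_drift"`.
#' @param kde_bandwidth KDE bandwidth for `method = "kde_drift"`.
#' @param epsilon Ridge regularization (default as in the solvers).
#' @param rank_tol Relative Gram truncation; default `1e-4`, heavier than the
#'   solver default because manifold data make the Gram matrix nearly
#'   singular and the fine-scale directions carry sampling noise only.
#' @param n_eig Number of eigenpairs computed (default `n_coords + 8`).
#' @return A `koop_embedding`: tibble `coordinates` (`phi1..phiK`), the
#'   spectrum, and the dropped-constant convention recorded.
#' @export
manifold_embedding <- function(data, kernel = NULL, n_coords = 2,
                               method = c("reversible", "kde_drift"),
                               kde_bandwidth = NULL, epsilon = NULL,
                               rank_tol = 1e-4, n_eig = NULL) {
  method <- match.arg(method)
  x <- as_points(data)
  n_eig <- n_eig %||% (n_coords + 8L)
  kernel <- kernel %||% gaussian_kernel(default_manifold_bandwidth(x), ncol(x))
  g0 <- assemble_g0(x, kernel)
  if (method == "reversible") {
    g1 <- assemble_g1(x, kernel, sqrt(2))
    spec <- solve_symmetric(g1, g0, epsilon = epsilon, n_eig = n_eig + 1,
                            rank_tol = rank_tol, points = x, kernel = kernel)
    phi <- Re(g0 %*% spec$coefficients)
    values <- -Re(spec$values)   # report eigenvalues of L itself
  } else {
    if (is.null(kde_bandwidth)) {
      stop_config("`kde_bandwidth` is required for method = \"kde_drift\".")
    }
    kde <- kde_fit(x, kde_bandwidth)
    b <- -kde_grad_logdensity(kde, x)
    # L = b . grad + Delta  (a = 2I at unit inverse temperature)
    coeffs <- coefficient_samples(x, a = -2, c1 = b)
    g2 <- assemble_g2(x, kernel, coeffs)
    spec <- solve_general(g2, g0, epsilon = epsilon, n_eig = n_eig + 1,
                          operator = "generator", rank_tol = rank_tol,
                          points = x, kernel = kernel)
    phi <- Re(g0 %*% spec$coefficients)
    values <- Re(spec$values)
  }
  keep <- seq(2L, min(n_eig + 1L, ncol(phi)))
  coords <- phi[, keep, drop = FALSE]
  colnames(coords) <- paste0("phi", seq_along(keep))
  structure(list(coordinates = tibble::as_tibble(coords),
                 values = values[keep], spectrum = spec, method = method,
                 kernel = kernel, n_coords = n_coords),
            class = "koop_embedding")
}

default_manifold_bandwidth <- function(x, subsample = 1000L) {
  m <- nrow(x)
  idx <- if (m > subsample) {
    round(seq(1L, m, length.out = subsample))
  } else {
    seq_len(m)
  }
  d2 <- pairwise_sqdist(x[idx, , drop = FALSE], x)
  d2[cbind(seq_along(idx), idx)] <- Inf
  0.75 * stats::median(sqrt(apply(d2, 1, min)))
}

#' @export
print.koop_embedding <- function(x, ...) {
  cat(sprintf("<koop_embedding> %d points, %d retained coordinates (%s estimator)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$method))
  invisible(x)
}
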