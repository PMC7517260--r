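# Benchmark systems, stochastic integrator and point-cloud samplers.
# Everything the estimators are exercised on is generated here; no external
# data are required.

#' Ornstein-Uhlenbeck model
#'
#' Overdamped Langevin dynamics in the quadratic potential
#' \eqn{V(x) = \tfrac{\alpha}{2} x^2}:
#' \eqn{dX_t = -\alpha X_t\,dt + \sqrt{2\beta^{-1}}\,dB_t}. The generator has
#' the known spectrum \eqn{\lambda_\ell = -\alpha\ell} with eigenfunctions
#' given by probabilists' Hermite polynomials
#' \eqn{\tilde H_\ell(\sqrt{\alpha\beta}\,x)}, which makes this the standard
#' analytic benchmark.
#'
#' @param alpha Friction coefficient (positive).
#' @param beta Inverse temperature (positive).
#' @return A `koop_sde`.
#' @export
ou_model <- function(alpha = 1, beta = 1) {
  if (alpha <= 0) stop_config("`alpha` must be positive.")
  langevin_model(
    potential = function(x) 0.5 * alpha * x[, 1]^2,
    grad_potential = function(x) alpha * x,
    hess_potential = function(x) matrix(alpha, 1, 1),
    beta = beta, d = 1, name = sprintf("ou(alpha=%g)", alpha),
    vectorized = TRUE)
}

#' Two-dimensional quadruple-well model
#'
#' Overdamped Langevin dynamics in
#' \eqn{V(x) = (x_1^2 - 1)^2 + (x_2^2 - 1)^2}, with four symmetric minima at
#' \eqn{(\pm 1, \pm 1)} separated by barriers of height 1 (saddles) and 2
#' (the origin). At the default inverse temperature \eqn{\beta = 1} the
#' negative generator has four dominant eigenvalues
#' \eqn{\{0, \nu, \nu, 2\nu\}} with \eqn{\nu \approx 0.75} (the pair is
#' exactly degenerate by the \eqn{x_1 \leftrightarrow x_2} symmetry), followed
#' by a spectral gap to the fast in-well relaxation modes near 6.
#'
#' @param beta Inverse temperature (default 1; see the methods vignette for
#'   why this value reproduces the benchmark spectrum).
#' @return A `koop_sde`.
#' @export
quadruple_well_model <- function(beta = 1) {
  if (beta <= 0) stop_config("`beta` must be positive.")
  langevin_model(
    potential = function(x) (x[, 1]^2 - 1)^2 + (x[, 2]^2 - 1)^2,
    grad_potential = function(x) 4 * x * (x^2 - 1),
    hess_potential = function(x) diag(4 * (3 * x^2 - 1)),
    beta = beta, d = 2, name = sprintf("quadruple_well(beta=%g)", beta),
    vectorized = TRUE)
}

#' Quantum harmonic oscillator
#'
#' Schrodinger model with \eqn{W(x) = \tfrac12 m\omega^2 x^2}. The energies
#' are \eqn{E_\ell = \hbar\omega(\ell + \tfrac12)} with Hermite-Gaussian
#' eigenfunctions; [qho_energies()] gives the closed form.
#'
#' @param hbar,mass,omega Physical constants (default 1).
#' @return A `koop_schrodinger`.
#' @export
qho_model <- function(hbar = 1, mass = 1, omega = 1) {
  if (omega <= 0) stop_config("`omega` must be positive.")
  schrodinger_model(
    potential = function(x) 0.5 * mass * omega^2 * x[, 1]^2,
    d = 1, hbar = hbar, mass = mass, name = "qho", vectorized = TRUE)
}

#' Analytic harmonic-oscillator energies
#'
#' @param l Vector of level indices (0-based).
#' @param hbar,omega Physical constants.
#' @return \eqn{E_\ell = \hbar\omega(\ell + 1/2)}.
#' @export
qho_energies <- function(l, hbar = 1, omega = 1) hbar * omega * (l + 0.5)

#' Hydrogen-atom model
#'
#' Schrodinger model in \eqn{R^3} with the Coulomb potential
#' \eqn{W(x) = -1/\|x\|} under unit physical constants
#' (\eqn{e = 4\pi\varepsilon_0 = \hbar = m = 1}). Samples within radius
#' `1e-8` of the origin are rejected by the pipelines (Coulomb singularity).
#' The exact spectrum \eqn{E_n = -1/(2n^2)} is \eqn{n^2}-fold degenerate,
#' which is the repeated-eigenvalue structure the kernel estimator should
#' reproduce.
#'
#' @return A `koop_schrodinger`.
#' @export
hydrogen_model <- function() {
  schrodinger_model(
    potential = function(x) {
      r <- sqrt(rowSums(x^2))
      ifelse(r < 1e-8, NA_real_, -1 / r)
    },
    d = 3, hbar = 1, mass = 1, singular_radius = 1e-8,
    name = "hydrogen", vectorized = TRUE)
}

#' Hydrogen ground state
#'
#' \eqn{\psi_0(x) \propto e^{-\|x\|/a_0}} with Bohr radius \eqn{a_0 = 1}
#' under unit constants, ground energy \eqn{E_0 = -1/2}; the drift of the dual
#' process is \eqn{-\nabla V = -(\hbar^2/(m a_0))\, x/\|x\|}.
#'
#' @param a0 Bohr radius (default 1).
#' @return A [ground_state()].
#' @export
hydrogen_ground_state <- function(a0 = 1) {
  ground_state(
    eta = function(x) sqrt(rowSums(x^2)) / a0,
    grad_eta = function(x) {
      r <- pmax(sqrt(rowSums(x^2)), 1e-12)
      x / (a0 * r)
    },
    energy = -0.5, d = 3, vectorized = TRUE)
}

#' Harmonic-oscillator ground state
#'
#' \eqn{\eta = \tfrac{m\omega}{2\hbar} x^2}, \eqn{E_0 = \hbar\omega/2}. The
#' dual process from [sde_from_ground_state()] is an Ornstein-Uhlenbeck
#' process with friction \eqn{\alpha = \hbar\omega}.
#'
#' @param hbar,mass,omega Physical constants.
#' @return A [ground_state()].
#' @export
qho_ground_state <- function(hbar = 1, mass = 1, omega = 1) {
  ground_state(
    eta = function(x) mass * omega / (2 * hbar) * x[, 1]^2,
    grad_eta = function(x) mass * omega / hbar * x,
    energy = hbar * omega / 2, d = 1, vectorized = TRUE)
}

#' Euler-Maruyama integration of a drift-diffusion model
#'
#' Integrates \eqn{x_{k+1} = x_k + b(x_k)\,dt + \sigma(x_k)\sqrt{dt}\,\xi_k}
#' with standard normal increments from a seeded stream, discards `burn_in`
#' steps and keeps every `stride`-th state thereafter. The defaults produce
#' approximately decorrelated samples from the invariant distribution when
#' `n_steps` is large enough for the system's slowest timescale.
#'
#' @param model A `koop_sde`.
#' @param x0 Initial state (`d`-vector).
#' @param n_steps Total number of integration steps.
#' @param dt Time step (default `1e-3`).
#' @param burn_in Discarded initial steps (default `1e4`).
#' @param stride Subsampling factor (default 1).
#' @param seed Optional integer seed (recorded in the result).
#' @return A `koop_trajectory`: a tibble with columns `x1..xd` and attributes
#'   `dt`, `stride`, `burn_in`, `seed`, `model_name`, and `sigma` (the
#'   constant diffusion matrix, when constant).
#' @export
euler_maruyama <- function(model, x0, n_steps, dt = 1e-3, burn_in = 1e4,
                           stride = 1, seed = NULL) {
  stopifnot(inherits(model, "koop_sde"))
  if (dt <= 0) stop_config("`dt` must be positive.")
  if (burn_in >= n_steps) stop_config("`burn_in` must be smaller than `n_steps`.")
  d <- model$d
  x0 <- check_vec(x0, d, "x0")
  keep <- seq(burn_in + stride, n_steps, by = stride)
  out <- matrix(0, length(keep), d)
  # tight closure over the drift to keep the per-step overhead small
  fdrift <- if (model$vectorized) {
    model$drift
  } else {
    function(x) matrix(as.numeric(model$drift(x[1, ])), 1, d)
  }
  with_seed(seed, {
    x <- matrix(x0, 1, d)
    sqdt <- sqrt(dt)
    sig_const <- model$sigma_constant
    sig <- if (sig_const) model$sigma else NULL
    ki <- 1L
    for (step in seq_len(n_steps)) {
      b <- fdrift(x)
      noise <- stats::rnorm(d)
      dx <- if (sig_const) sig %*% noise else {
        diffusion_at(model, x)[1, , ] %*% noise
      }
      x <- x + b * dt + sqdt * matrix(dx, 1, d)
      if (!all(is.finite(x))) {
        stop_numerical("trajectory blew up (non-finite state) at step %d.", step)
      }
      if (ki <= length(keep) && step == keep[ki]) {
        out[ki, ] <- x
        ki <- ki + 1L
      }
    }
  })
  colnames(out) <- paste0("x", seq_len(d))
  traj <- tibble::as_tibble(out)
  attr(traj, "dt") <- dt
  attr(traj, "stride") <- stride
  attr(traj, "burn_in") <- burn_in
  attr(traj, "seed") <- seed
  attr(traj, "model_name") <- model$name
  if (model$sigma_constant) attr(traj, "sigma") <- model$sigma
  class(traj) <- c("koop_trajectory", class(traj))
  traj
}

#' Uniform samples in a box
#'
#' @param lower,upper Bounds (`d`-vectors or scalars recycled to `d`).
#' @param n Number of samples.
#' @param d Dimension (inferred from the bounds if omitted).
#' @param seed Optional integer seed.
#' @return Tibble with columns `x1..xd`.
#' @export
sample_uniform_box <- function(lower, upper, n, d = NULL, seed = NULL) {
  d <- d %||% max(length(lower), length(upper))
  lower <- rep_len(lower, d); upper <- rep_len(upper, d)
  if (any(upper <= lower)) stop_config("degenerate box: `upper` must exceed `lower`.")
  if (n < 1) stop_config("`n` must be at least 1.")
  pts <- with_seed(seed, {
    vapply(seq_len(d), function(i) stats::runif(n, lower[i], upper[i]),
           numeric(n))
  })
  pts <- matrix(pts, nrow = n)
  colnames(pts) <- paste0("x", seq_len(d))
  tibble::as_tibble(pts)
}

#' Uniform samples in a ball
#'
#' Draws uniformly from the `d`-ball of given radius via a normalized Gaussian
#' direction times \eqn{\mathrm{radius}\cdot U^{1/d}}.
#'
#' @param radius Ball radius (positive).
#' @param n Number of samples.
#' @param d Dimension.
#' @param seed Optional integer seed.
#' @return Tibble with columns `x1..xd`.
#' @export
sample_uniform_ball <- function(radius, n, d, seed = NULL) {
  if (radius <= 0) stop_config("`radius` must be positive.")
  if (n < 1) stop_config("`n` must be at least 1.")
  d <- check_dimension(d)
  pts <- with_seed(seed, {
    z <- matrix(stats::rnorm(n * d), n, d)
    z <- z / pmax(sqrt(rowSums(z^2)), 1e-300)
    r <- radius * stats::runif(n)^(1 / d)
    z * r
  })
  colnames(pts) <- paste0("x", seq_len(d))
  tibble::as_tibble(pts)
}

#' Swiss-roll sample
#'
#' The classic two-dimensional manifold embedded in \eqn{R^3}: with angle
#' \eqn{t \sim U[1.5\pi, 4.5\pi]} and height \eqn{h \sim U[0, 21]}, the points
#' are \eqn{(t\cos t,\; h,\; t\sin t)}. The latent coordinates are returned
#' alongside the ambient ones for validation only; the estimators never see
#' them.
#'
#' @param n Number of samples.
#' @param seed Optional integer seed.
#' @return Tibble with ambient columns `x1, x2, x3` and latent columns
#'   `angle`, `height`.
#' @export
swiss_roll_sample <- function(n, seed = NULL) {
  if (n < 1) stop_config("`n` must be at least 1.")
  with_seed(seed, {
    t <- stats::runif(n, 1.5 * pi, 4.5 * pi)
    h <- stats::runif(n, 0, 21)
    tibble::tibble(x1 = t * cos(t), x2 = h, x3 = t * sin(t),
                   angle = t, height = h)
  })
}

#' Probabilists' Hermite polynomials
#'
#' \eqn{\tilde H_\ell} by the three-term recurrence; used to compare estimated
#' Ornstein-Uhlenbeck eigenfunctions against their closed form
#' \eqn{\varphi_\ell(x) = \tilde H_\ell(\sqrt{\alpha\beta}\,x)}.
#'
#' @param x Evaluation points.
#' @param l Degree (0-based).
#' @return Vector of polynomial values.
#' @export
hermite_probabilists <- function(x, l) {
  if (l == 0) return(rep(1, length(x)))
  if (l == 1) return(x)
  hm2 <- rep(1, length(x)); hm1 <- x
  for (k in 2:l) {
    h <- x * hm1 - (k - 1) * hm2
    hm2 <- hm1; hm1 <- h
  }
  hm1
}
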