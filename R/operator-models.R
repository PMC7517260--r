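# Coefficient fields of the operators handled by the package and the exact
# transforms between them: drift-diffusion (Koopman) generators, general
# elliptic operators, Schrodinger operators, and the ground-state duality
# that maps one into the other.

#' Drift-diffusion model
#'
#' Represents the stochastic differential equation
#' \eqn{dX_t = b(X_t)\,dt + \sigma(X_t)\,dB_t} whose Koopman generator is
#' \eqn{Lf = b\cdot\nabla f + \tfrac12 \sum_{ij} a_{ij}\,\partial_i\partial_j f}
#' with \eqn{a = \sigma\sigma^\top}.
#'
#' @param drift Drift field `b`: function of a point (or of an `M x d` matrix
#'   if `vectorized = TRUE`) returning a `d`-vector (matrix).
#' @param diffusion Diffusion `sigma`: a constant `d x d` matrix, a scalar
#'   (meaning `scalar * I`), or a function of a point returning a `d x d`
#'   matrix.
#' @param d State-space dimension.
#' @param potential,grad_potential,hess_potential Optional potential `V`, its
#'   gradient and (pointwise) Hessian, for gradient systems.
#' @param beta Optional inverse temperature (positive).
#' @param name Display name.
#' @param vectorized Whether `drift`/`potential`/`grad_potential` accept an
#'   `M x d` matrix of points at once.
#' @return A `koop_sde` object.
#' @seealso [langevin_model()], [ou_model()], [quadruple_well_model()]
#' @export
drift_diffusion_model <- function(drift, diffusion, d,
                                  potential = NULL, grad_potential = NULL,
                                  hess_potential = NULL, beta = NULL,
                                  name = "drift-diffusion", vectorized = FALSE) {
  d <- check_dimension(d)
  sigma_constant <- !is.function(diffusion)
  if (sigma_constant) {
    if (length(diffusion) == 1L) diffusion <- diag(as.numeric(diffusion), d)
    diffusion <- as.matrix(diffusion)
    if (!identical(dim(diffusion), c(d, d))) {
      stop_config("constant `diffusion` must be a d x d matrix or a scalar.")
    }
  }
  if (!is.null(beta) && beta <= 0) stop_config("`beta` must be positive.")
  structure(list(
    d = d, name = name, drift = drift,
    sigma = diffusion, sigma_constant = sigma_constant,
    a_const = if (sigma_constant) tcrossprod(diffusion) else NULL,
    potential = potential, grad_potential = grad_potential,
    hess_potential = hess_potential, beta = beta,
    vectorized = vectorized
  ), class = "koop_sde")
}

#' Overdamped Langevin model
#'
#' The reversible gradient system
#' \eqn{dX_t = -\nabla V(X_t)\,dt + \sqrt{2\beta^{-1}}\,dB_t}, whose generator
#' is \eqn{Lf = -\nabla V\cdot\nabla f + \beta^{-1}\Delta f} and whose
#' invariant density is \eqn{\rho_0 \propto e^{-\beta V}} (generalized
#' potential \eqn{F = \beta V}).
#'
#' @param potential Potential `V`.
#' @param grad_potential Gradient of `V`.
#' @param beta Inverse temperature (positive).
#' @param d State-space dimension.
#' @param hess_potential Optional pointwise Hessian of `V` (used by the
#'   generator-to-Schrodinger transform; finite differences otherwise).
#' @inheritParams drift_diffusion_model
#' @return A `koop_sde` with `b = -grad V`, `sigma = sqrt(2/beta) I`,
#'   `a = 2/beta I`, and `(V, beta)` retained.
#' @export
langevin_model <- function(potential, grad_potential, beta, d,
                           hess_potential = NULL, name = "langevin",
                           vectorized = FALSE) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
    stop_config("`beta` must be a single positive number.")
  }
  drift <- if (vectorized) {
    function(x) -grad_potential(x)
  } else {
    function(x) -as.numeric(grad_potential(x))
  }
  drift_diffusion_model(
    drift = drift, diffusion = diag(sqrt(2 / beta), check_dimension(d)), d = d,
    potential = potential, grad_potential = grad_potential,
    hess_potential = hess_potential, beta = beta, name = name,
    vectorized = vectorized)
}

#' @export
print.koop_sde <- function(x, ...) {
  cat(sprintf("<koop_sde> '%s' on R^%d%s%s\n", x$name, x$d,
              if (!is.null(x$beta)) sprintf(", beta = %g", x$beta) else "",
              if (x$sigma_constant) ", constant diffusion" else ""))
  invisible(x)
}

# Field accessors (always M x d matrix in, vectorized out) ------------------

drift_at <- function(model, x) {
  x <- as_points(x, model$d)
  eval_field(model$drift, x, "vector", model$vectorized)
}

diffusion_at <- function(model, x) {
  x <- as_points(x, model$d)
  if (model$sigma_constant) {
    out <- array(0, c(nrow(x), model$d, model$d))
    for (i in seq_len(nrow(x))) out[i, , ] <- model$sigma
    return(out)
  }
  eval_field(model$sigma, x, "matrix", vectorized = FALSE)
}

potential_at <- function(model, x) {
  x <- as_points(x, model$d)
  if (is.null(model$potential)) stop_config("model has no potential.")
  eval_field(model$potential, x, "scalar", model$vectorized)
}

grad_potential_at <- function(model, x) {
  x <- as_points(x, model$d)
  if (is.null(model$grad_potential)) stop_config("model has no potential gradient.")
  eval_field(model$grad_potential, x, "vector", model$vectorized)
}

#' General elliptic operator model
#'
#' The operator
#' \eqn{T = -\tfrac12 e^{F}\,\nabla\cdot(e^{-F} a\,\nabla\,\cdot) + J\cdot\nabla + W}
#' acting on \eqn{L^2_\mu} with \eqn{\rho_0 \propto e^{-F}}. Setting
#' \eqn{F \equiv 0} gives a generalized Schrodinger operator; with
#' \eqn{W \equiv 0} and the stationary-flow `J` of a drift-diffusion model it
#' is the negative Koopman generator. Only constant diffusion fields `a` are
#' supported directly (the divergence term vanishes); position-dependent `a`
#' requires a user-supplied divergence through `div_a`.
#'
#' @param a Constant `d x d` symmetric positive definite matrix (or scalar
#'   meaning `scalar * I`).
#' @param d State-space dimension.
#' @param flow Optional flow field `J` (function; `NULL` means zero).
#' @param F_fun,grad_F Optional generalized potential and gradient.
#' @param W_fun Optional zeroth-order (multiplication) term.
#' @param div_a Optional column-wise divergence of `a` (only needed for
#'   non-constant `a`; unsupported otherwise).
#' @param vectorized Whether the supplied functions are row-vectorized.
#' @return A `koop_elliptic` object.
#' @export
elliptic_operator_model <- function(a, d, flow = NULL, F_fun = NULL,
                                    grad_F = NULL, W_fun = NULL,
                                    div_a = NULL, vectorized = FALSE) {
  d <- check_dimension(d)
  if (is.function(a) && is.null(div_a)) {
    stop_config("position-dependent `a` requires a `div_a` evaluator.")
  }
  if (!is.function(a)) {
    if (length(a) == 1L) a <- diag(as.numeric(a), d)
    a <- as.matrix(a)
    if (!isSymmetric(a, tol = 1e-10)) stop_config("`a` must be symmetric.")
    if (min(eigen(a, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop_config("`a` must be positive definite.")
    }
  }
  structure(list(d = d, a = a, a_constant = !is.function(a), flow = flow,
                 F_fun = F_fun, grad_F = grad_F, W_fun = W_fun,
                 div_a = div_a, vectorized = vectorized),
            class = "koop_elliptic")
}

#' Schrodinger operator model
#'
#' The Hamiltonian \eqn{H = -\frac{\hbar^2}{2m}\Delta + W} of the
#' time-independent Schrodinger equation \eqn{H\psi = E\psi}. Internally this
#' is the elliptic operator with \eqn{a = (\hbar^2/m) I}, \eqn{J \equiv 0} and
#' \eqn{F \equiv 0}.
#'
#' @param potential Potential energy `W` (function of a point, or of a point
#'   matrix if `vectorized = TRUE`).
#' @param d State-space dimension.
#' @param hbar Reduced Planck constant (default 1).
#' @param mass Particle mass (default 1).
#' @param singular_radius Samples closer than this to a potential singularity
#'   are rejected by the pipelines (e.g. the Coulomb origin); 0 disables.
#' @param name Display name.
#' @param vectorized Whether `potential` is row-vectorized.
#' @return A `koop_schrodinger` object.
#' @export
schrodinger_model <- function(potential, d, hbar = 1, mass = 1,
                              singular_radius = 0, name = "schrodinger",
                              vectorized = FALSE) {
  if (hbar <= 0 || mass <= 0) stop_config("`hbar` and `mass` must be positive.")
  d <- check_dimension(d)
  structure(list(d = d, potential = potential, hbar = hbar, mass = mass,
                 singular_radius = singular_radius, name = name,
                 vectorized = vectorized),
            class = "koop_schrodinger")
}

#' @export
print.koop_schrodinger <- function(x, ...) {
  cat(sprintf("<koop_schrodinger> '%s' on R^%d, hbar = %g, m = %g\n",
              x$name, x$d, x$hbar, x$mass))
  invisible(x)
}

schrodinger_potential_at <- function(model, x) {
  x <- as_points(x, model$d)
  eval_field(model$potential, x, "scalar", model$vectorized)
}

#' Ground-state specification
#'
#' A strictly positive ground state written as \eqn{\psi_0 = e^{-\eta}},
#' together with the ground energy \eqn{E_0}. This is the data needed to map a
#' Schrodinger operator to the Koopman generator of a drift-diffusion process
#' (see [sde_from_ground_state()]) and back (see [spectrum_transform()]).
#'
#' @param eta Log ground state `eta` (function of a point).
#' @param grad_eta Gradient of `eta`.
#' @param energy Ground-state energy `E0`.
#' @param d State-space dimension.
#' @param vectorized Whether `eta`/`grad_eta` are row-vectorized.
#' @return A `koop_ground_state` object with a `psi0` evaluator.
#' @export
ground_state <- function(eta, grad_eta, energy, d, vectorized = FALSE) {
  d <- check_dimension(d)
  structure(list(eta = eta, grad_eta = grad_eta, energy = energy, d = d,
                 vectorized = vectorized),
            class = "koop_ground_state")
}

psi0_at <- function(gs, x) {
  x <- as_points(x, gs$d)
  exp(-eval_field(gs$eta, x, "scalar", gs$vectorized))
}

#' Stationary probability flow
#'
#' The vector field
#' \eqn{J = \tfrac12 e^{F}\,\nabla\cdot(e^{-F} a) - b} measuring the
#' irreversible part of a drift-diffusion process with invariant density
#' \eqn{\rho_0 \propto e^{-F}}. For constant `a` this reduces to
#' \eqn{J = -\tfrac12 a\,\nabla F - b}; it vanishes identically for
#' reversible (gradient) systems with \eqn{F = \beta V}.
#'
#' @param model A `koop_sde`. Only constant diffusion is supported (the
#'   divergence term is zero); position-dependent diffusion needs divergence
#'   information the model cannot provide.
#' @param F_fun,grad_F Generalized potential and gradient; default to
#'   \eqn{\beta V} for models carrying `(V, beta)`.
#' @return A row-vectorized evaluator: `M x d` matrix of points in,
#'   `M x d` matrix of flow vectors out.
#' @export
stationary_flow <- function(model, F_fun = NULL, grad_F = NULL) {
  stopifnot(inherits(model, "koop_sde"))
  if (!model$sigma_constant) {
    stop_config(paste0("stationary_flow supports constant diffusion only; ",
                       "supply divergence information via an elliptic model."))
  }
  if (is.null(grad_F)) {
    if (is.null(model$grad_potential) || is.null(model$beta)) {
      stop_config("no `grad_F` given and the model carries no (V, beta) pair.")
    }
    beta <- model$beta
    gp <- function(x) beta * grad_potential_at(model, x)
  } else {
    vec <- model$vectorized
    gp <- function(x) eval_field(grad_F, as_points(x, model$d), "vector", vec)
  }
  a <- model$a_const
  function(x) {
    x <- as_points(x, model$d)
    -0.5 * gp(x) %*% a - drift_at(model, x)
  }
}

#' Schrodinger potential of a generator (unitary equivalence)
#'
#' Builds the potential
#' \eqn{W = -\tfrac14 \nabla\cdot(a\nabla F) + \tfrac18 \nabla F^\top a \nabla F
#' + \tfrac12 J\cdot\nabla F}
#' for which \eqn{H = -\tfrac12\nabla\cdot a\nabla + J\cdot\nabla + W} is
#' unitarily equivalent to the negative generator with invariant density
#' \eqn{\propto e^{-F}}; the function \eqn{e^{-F/2}} is then an eigenfunction
#' of `H` with eigenvalue zero (a property checked numerically by
#' [annihilation_residual()]).
#'
#' @param F_fun Generalized potential `F` (function of a point).
#' @param grad_F Gradient of `F`.
#' @param a Constant diffusion matrix (or scalar meaning `scalar * I`).
#' @param d State-space dimension.
#' @param flow Optional flow field `J` (default zero).
#' @param hess_F Optional pointwise Hessian of `F`; central finite differences
#'   of `grad_F` (step `1e-5`) are used when absent.
#' @return Row-vectorized evaluator of `W` (point matrix in, vector out).
#' @export
schrodinger_from_generator <- function(F_fun, grad_F, a, d, flow = NULL,
                                       hess_F = NULL) {
  d <- check_dimension(d)
  if (length(a) == 1L) a <- diag(as.numeric(a), d)
  a <- as.matrix(a)
  if (min(eigen(a, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop_config("`a` must be positive definite.")
  }
  hess <- hess_F %||% function(x) {
    jac <- vapply(seq_len(d), function(i) {
      e <- numeric(d); e[i] <- 1e-5
      (as.numeric(grad_F(x + e)) - as.numeric(grad_F(x - e))) / 2e-5
    }, numeric(d))
    (jac + t(jac)) / 2
  }
  function(x) {
    x <- as_points(x, d)
    vapply(seq_len(nrow(x)), function(m) {
      xm <- x[m, ]
      g <- as.numeric(grad_F(xm))
      w <- -0.25 * sum(a * hess(xm)) + 0.125 * sum(g * (a %*% g))
      if (!is.null(flow)) w <- w + 0.5 * sum(as.numeric(flow(xm)) * g)
      w
    }, numeric(1))
  }
}

#' Residual of the ground-state annihilation identity
#'
#' Applies \eqn{H = -\tfrac12 \nabla\cdot a\nabla + J\cdot\nabla + W} (constant
#' `a`, `J = 0`) to \eqn{e^{-F/2}} by central finite differences on a grid of
#' evaluation points and returns the residual values, which should vanish when
#' `W` comes from [schrodinger_from_generator()].
#'
#' @param F_fun Generalized potential.
#' @param W_fun Potential of the candidate Schrodinger operator.
#' @param a Constant diffusion matrix (or scalar).
#' @param grid `M x d` matrix of evaluation points.
#' @param h Finite-difference step for the Laplacian (default `1e-3`).
#' @return Vector of residuals \eqn{(H e^{-F/2})(x)} at the grid points.
#' @export
annihilation_residual <- function(F_fun, W_fun, a, grid, h = 1e-3) {
  grid <- as_points(grid)
  d <- ncol(grid)
  if (length(a) == 1L) a <- diag(as.numeric(a), d)
  f <- function(x) exp(-0.5 * as.numeric(F_fun(x)))
  w <- as.numeric(W_fun(grid))
  vapply(seq_len(nrow(grid)), function(m) {
    xm <- grid[m, ]
    lap <- 0
    for (i in seq_len(d)) {
      for (j in seq_len(d)) {
        if (a[i, j] == 0) next
        ei <- numeric(d); ei[i] <- h
        ej <- numeric(d); ej[j] <- h
        dij <- if (i == j) {
          (f(xm + ei) - 2 * f(xm) + f(xm - ei)) / h^2
        } else {
          (f(xm + ei + ej) - f(xm + ei - ej) - f(xm - ei + ej) +
             f(xm - ei - ej)) / (4 * h^2)
        }
        lap <- lap + a[i, j] * dij
      }
    }
    -0.5 * lap + w[m] * f(xm)
  }, numeric(1))
}

#' Drift-diffusion process associated with a ground state
#'
#' Given a strictly positive ground state \eqn{\psi_0 = e^{-\eta}} of a
#' Schrodinger operator, returns the overdamped Langevin model with potential
#' \eqn{V = (\hbar^2/m)\,\eta} (up to an additive constant, which cancels in
#' the drift) and inverse temperature \eqn{\beta^{-1} = \hbar^2/(2m)}, i.e.
#' \eqn{b = -(\hbar^2/m)\nabla\eta} and \eqn{a = (\hbar^2/m) I}. The Koopman
#' generator of this process carries the full Schrodinger spectrum through
#' [spectrum_transform()].
#'
#' @param gs A [ground_state()].
#' @param hbar,mass Physical constants (positive; default 1).
#' @return A `koop_sde` (Langevin form).
#' @export
sde_from_ground_state <- function(gs, hbar = 1, mass = 1) {
  stopifnot(inherits(gs, "koop_ground_state"))
  if (hbar <= 0 || mass <= 0) stop_config("`hbar` and `mass` must be positive.")
  kap <- hbar^2 / mass
  eta <- gs$eta; geta <- gs$grad_eta
  langevin_model(
    potential = function(x) kap * eta(x),
    grad_potential = function(x) kap * geta(x),
    beta = 2 * mass / hbar^2, d = gs$d,
    name = "ground-state dual", vectorized = gs$vectorized)
}

#' Schrodinger spectrum from generator eigenvalues
#'
#' Converts a spectral result for the Koopman generator `L` of the
#' ground-state dual process into Schrodinger energies
#' \eqn{E_\ell = E_0 - \lambda_\ell} and wavefunction evaluators
#' \eqn{\psi_\ell = \psi_0 \varphi_\ell}.
#'
#' @param spectrum A `koop_spectrum` for the generator (eigenvalues with
#'   nonpositive real parts, sorted descending so the stationary eigenvalue
#'   comes first).
#' @param gs The [ground_state()] used to build the dual process.
#' @return A `koop_wavefunctions` object with fields `energies` (real parts),
#'   `spectrum` and `ground_state`; evaluate with [evaluate_wavefunctions()].
#' @export
spectrum_transform <- function(spectrum, gs) {
  stopifnot(inherits(spectrum, "koop_spectrum"),
            inherits(gs, "koop_ground_state"))
  structure(list(energies = gs$energy - Re(spectrum$values),
                 spectrum = spectrum, ground_state = gs),
            class = "koop_wavefunctions")
}

#' @export
print.koop_wavefunctions <- function(x, ...) {
  cat("<koop_wavefunctions>", length(x$energies), "energy levels:",
      paste(sprintf("%.4g", utils::head(x$energies, 6)), collapse = ", "),
      if (length(x$energies) > 6) "..." else "", "\n")
  invisible(x)
}

#' Evaluate transformed wavefunctions
#'
#' Evaluates \eqn{\psi_\ell = \psi_0 \varphi_\ell} at query points, scaling
#' each wavefunction to unit empirical mean square over those points. The
#' probability densities are \eqn{p_\ell = |\psi_\ell|^2}.
#'
#' @param wf A `koop_wavefunctions` from [spectrum_transform()].
#' @param newdata Query points (matrix or data frame).
#' @param normalize Scale columns to unit empirical mean square (default TRUE).
#' @return `R x K` matrix of wavefunction values.
#' @export
evaluate_wavefunctions <- function(wf, newdata, normalize = TRUE) {
  stopifnot(inherits(wf, "koop_wavefunctions"))
  x <- as_points(newdata, wf$spectrum$kernel$d)
  phi <- Re(evaluate_eigenfunctions(wf$spectrum, x))
  psi <- psi0_at(wf$ground_state, x) * phi
  if (normalize) {
    scl <- sqrt(colMeans(psi^2))
    scl[scl == 0] <- 1
    psi <- sweep(psi, 2, scl, "/")
  }
  psi
}

#' First-order coefficient of the assembled operator
#'
#' The coefficient
#' \eqn{c_1 = J - \tfrac12 e^{F}\nabla\cdot(e^{-F} a)} multiplying the
#' first-order kernel derivatives in the Gram matrix `G2`. For a
#' drift-diffusion generator written through its stationary decomposition this
#' equals \eqn{-b} identically; for a Schrodinger model (no flow, constant
#' diffusion, flat `F`) it vanishes.
#'
#' @param model A `koop_sde`, `koop_elliptic` or `koop_schrodinger`.
#' @return Row-vectorized evaluator (point matrix in, `M x d` matrix out).
#' @export
first_order_coefficient <- function(model) {
  if (inherits(model, "koop_sde")) {
    return(function(x) -drift_at(model, x))
  }
  if (inherits(model, "koop_schrodinger")) {
    d <- model$d
    return(function(x) matrix(0, nrow(as_points(x, d)), d))
  }
  if (inherits(model, "koop_elliptic")) {
    if (!model$a_constant) {
      stop_config("first_order_coefficient with non-constant `a` requires `div_a`.")
    }
    d <- model$d; a <- model$a
    gF <- model$grad_F; J <- model$flow; vec <- model$vectorized
    return(function(x) {
      x <- as_points(x, d)
      out <- matrix(0, nrow(x), d)
      if (!is.null(gF)) out <- out + 0.5 * eval_field(gF, x, "vector", vec) %*% a
      if (!is.null(J)) out <- out + eval_field(J, x, "vector", vec)
      out
    })
  }
  stop_config("unsupported model class for first_order_coefficient().")
}
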