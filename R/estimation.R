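# Empirical Gram matrices and the two generalized eigenvalue problems at the
# heart of the package, plus the explicit-dictionary gEDMD route used as an
# independent cross-check when the feature space is finite and known.

#' Coefficient samples of an elliptic operator
#'
#' Collects the operator coefficients evaluated at the training points, in the
#' convention of the assembled operator
#' \eqn{T = -\tfrac12\sum_{ij} a_{ij}\partial_i\partial_j + c_1\cdot\nabla + W}:
#' second-order field `a`, first-order coefficient `c1` (equal to \eqn{-b} for
#' a drift-diffusion generator written through its stationary decomposition)
#' and multiplication term `w`.
#'
#' @param points `M x d` training points.
#' @param a Second-order coefficient: scalar (meaning `scalar * I`), `d`-vector
#'   (diagonal), constant `d x d` matrix, `M x d x d` array of per-point
#'   matrices, or a function of a point returning a `d x d` matrix.
#' @param c1 First-order coefficient: `M x d` matrix, constant `d`-vector, or
#'   function of a point returning a `d`-vector; `NULL` means zero.
#' @param w Multiplication term: length-`M` vector, scalar, or function;
#'   `NULL` means zero.
#' @return A `koop_coefficients` object.
#' @seealso [operator_coefficients()] for extraction from model objects.
#' @export
coefficient_samples <- function(points, a, c1 = NULL, w = NULL) {
  x <- as_points(points)
  m <- nrow(x); d <- ncol(x)
  a_arr <- coerce_a(a, x)
  c1_mat <- if (is.null(c1)) {
    matrix(0, m, d)
  } else if (is.function(c1)) {
    eval_field(c1, x, "vector")
  } else if (is.matrix(c1)) {
    stopifnot(nrow(c1) == m, ncol(c1) == d); c1
  } else {
    matrix(as.numeric(c1), m, d, byrow = TRUE)
  }
  w_vec <- if (is.null(w)) {
    numeric(m)
  } else if (is.function(w)) {
    eval_field(w, x, "scalar")
  } else {
    rep_len(as.numeric(w), m)
  }
  structure(list(points = x, a = a_arr, c1 = c1_mat, w = w_vec, m = m, d = d),
            class = "koop_coefficients")
}

coerce_a <- function(a, x) {
  m <- nrow(x); d <- ncol(x)
  if (is.function(a)) return(eval_field(a, x, "matrix"))
  if (is.array(a) && length(dim(a)) == 3L) {
    stopifnot(all(dim(a) == c(m, d, d)))
    return(a)
  }
  amat <- if (length(a) == 1L) {
    diag(as.numeric(a), d)
  } else if (is.null(dim(a))) {
    stopifnot(length(a) == d); diag(as.numeric(a), d)
  } else {
    as.matrix(a)
  }
  stopifnot(all(dim(amat) == c(d, d)))
  out <- array(0, c(m, d, d))
  for (i in seq_len(m)) out[i, , ] <- amat
  out
}

#' Coefficient samples for a model and operator convention
#'
#' Evaluates the coefficient fields of a model at the training points, signed
#' for the requested operator: `"negative_generator"` gives
#' \eqn{T = -L} (`c1 = -b`, second-order \eqn{-\tfrac12 a} convention),
#' `"generator"` gives `L` itself, and `"schrodinger"` gives
#' \eqn{H = -\frac{\hbar^2}{2m}\Delta + W}.
#'
#' @param model A `koop_sde`, `koop_elliptic` or `koop_schrodinger`.
#' @param points Training points.
#' @param operator Operator convention (see Details).
#' @return A `koop_coefficients` object suitable for [assemble_g2()].
#' @export
operator_coefficients <- function(model, points,
                                  operator = c("negative_generator",
                                               "generator", "schrodinger",
                                               "elliptic")) {
  operator <- match.arg(operator)
  x <- as_points(points)
  if (inherits(model, "koop_schrodinger")) {
    if (!operator %in% c("schrodinger", "elliptic")) {
      stop_config("a Schrodinger model defines the operator H, not a generator.")
    }
    return(coefficient_samples(
      x, a = (model$hbar^2 / model$mass),
      c1 = NULL, w = schrodinger_potential_at(model, x)))
  }
  if (inherits(model, "koop_elliptic")) {
    c1f <- first_order_coefficient(model)
    wv <- if (is.null(model$W_fun)) NULL else {
      eval_field(model$W_fun, x, "scalar", model$vectorized)
    }
    return(coefficient_samples(x, a = model$a, c1 = c1f(x), w = wv))
  }
  if (!inherits(model, "koop_sde")) {
    stop_config("unsupported model class for operator_coefficients().")
  }
  b <- drift_at(model, x)
  a_arr <- if (model$sigma_constant) {
    coerce_a(model$a_const, x)
  } else {
    sig <- diffusion_at(model, x)
    a <- array(0, dim(sig))
    for (i in seq_len(nrow(x))) a[i, , ] <- tcrossprod(sig[i, , ])
    a
  }
  if (operator == "generator") {
    coefficient_samples(x, a = -a_arr, c1 = b, w = NULL)
  } else {
    coefficient_samples(x, a = a_arr, c1 = -b, w = NULL)
  }
}

#' Standard Gram matrix G0
#'
#' `G0[m, r] = k(x_m, x_r)`; symmetric positive semidefinite.
#'
#' @param points `M x d` training points.
#' @param kernel A `koop_kernel`.
#' @return `M x M` matrix.
#' @export
assemble_g0 <- function(points, kernel) {
  x <- as_points(points, kernel$d)
  g0 <- kernel_matrix(kernel, x, x)
  (g0 + t(g0)) / 2
}

#' Diffusion-weighted gradient Gram matrices G1
#'
#' For each column \eqn{\sigma_l} of the diffusion field,
#' `G1[[l]][m, r] =` \eqn{\sigma_l(x_m)^\top \nabla_1 k(x_m, x_r)}. Only these
#' first-order matrices (plus `G0`) are needed by the reversible estimator, so
#' equilibrated trajectory data and the diffusion term suffice -- no drift
#' estimates.
#'
#' @param points `M x d` training points.
#' @param kernel A `koop_kernel`.
#' @param sigma Diffusion: scalar, constant `d x d` matrix, `M x d x d` array
#'   or function of a point returning a `d x d` matrix.
#' @return List of `d` matrices of size `M x M`.
#' @export
assemble_g1 <- function(points, kernel, sigma) {
  x <- as_points(points, kernel$d)
  d <- ncol(x)
  sig <- coerce_a(sigma, x)  # M x d x d, rows sigma(x_m)
  lapply(seq_len(d), function(l) {
    g <- matrix(0, nrow(x), nrow(x))
    for (i in seq_len(d)) {
      sil <- sig[, i, l]
      if (all(sil == 0)) next
      alpha <- integer(d); alpha[i] <- 1L
      g <- g + sil * kernel_matrix(kernel, x, x, alpha)
    }
    g
  })
}

#' Operator-applied Gram matrix G2
#'
#' `G2[m, r]` applies the operator
#' \eqn{T = -\tfrac12\sum_{ij} a_{ij}\partial_i\partial_j + c_1\cdot\nabla + W}
#' in the first kernel slot at each training point:
#' \deqn{G2_{mr} = -\tfrac12\sum_{ij} a_{ij}(x_m) D^{e_i+e_j}k(x_m, x_r)
#'   + \sum_i c_{1,i}(x_m) D^{e_i}k(x_m, x_r) + W(x_m)\,k(x_m, x_r).}
#'
#' @param points `M x d` training points.
#' @param kernel A `koop_kernel`.
#' @param coeffs A [coefficient_samples()] object (or arguments for it via
#'   [operator_coefficients()]).
#' @return `M x M` matrix.
#' @export
assemble_g2 <- function(points, kernel, coeffs) {
  x <- as_points(points, kernel$d)
  stopifnot(inherits(coeffs, "koop_coefficients"))
  if (coeffs$m != nrow(x)) stop_config("coefficient samples do not match points.")
  d <- ncol(x)
  g2 <- matrix(0, nrow(x), nrow(x))
  for (i in seq_len(d)) {
    for (j in i:d) {
      aij <- coeffs$a[, i, j]
      if (all(aij == 0)) next
      alpha <- integer(d); alpha[i] <- alpha[i] + 1L; alpha[j] <- alpha[j] + 1L
      fac <- if (i == j) -0.5 else -1  # symmetry of a folds the (j, i) term in
      g2 <- g2 + fac * aij * kernel_matrix(kernel, x, x, alpha)
    }
  }
  for (i in seq_len(d)) {
    c1i <- coeffs$c1[, i]
    if (all(c1i == 0)) next
    alpha <- integer(d); alpha[i] <- 1L
    g2 <- g2 + c1i * kernel_matrix(kernel, x, x, alpha)
  }
  if (any(coeffs$w != 0)) {
    g2 <- g2 + coeffs$w * kernel_matrix(kernel, x, x)
  }
  g2
}

default_epsilon <- function(g0) 1e-8 * mean(diag(g0))

# Dominant-eigenspace decomposition of G0 used by both solvers. Directions
# whose Gram eigenvalue is numerically negligible carry no function-space
# information but amplify noise into spurious eigenvalues of the pencil, so
# they are truncated before the pencil is formed.
g0_basis <- function(g0, rank_tol, squared = FALSE) {
  e <- eigen(g0, symmetric = TRUE)
  rel <- e$values / max(e$values)
  keep <- if (squared) rel^2 > rank_tol else rel > rank_tol
  keep <- keep & e$values > 0
  if (!any(keep)) stop_numerical("Gram matrix is numerically zero.")
  list(q = e$vectors[, keep, drop = FALSE], lambda = e$values[keep],
       rank = sum(keep))
}

#' Solve the general (non-symmetric) eigenvalue problem
#'
#' Solves the pencil \eqn{G_2 u = \hat\lambda (G_0 + \epsilon I) u} restricted
#' to the dominant eigenspace of `G0` (relative truncation `rank_tol`).
#' Eigenfunctions are \eqn{\varphi = \Phi u}; complex pairs are preserved.
#' Results for a generator are sorted by descending real part (the stationary
#' eigenvalue 0 first); for `"schrodinger"`/`"negative_generator"` operators
#' by ascending real part (ground state first).
#'
#' @param g2,g0 Gram matrices from [assemble_g2()] and [assemble_g0()].
#' @param epsilon Ridge added to the mass matrix; default
#'   `1e-8 * mean(diag(G0))`.
#' @param n_eig Number of eigenpairs to return.
#' @param operator `"generator"`, `"negative_generator"` or `"schrodinger"`
#'   (controls the sort order and is recorded in the result).
#' @param rank_tol Relative truncation threshold for the `G0` eigenspace.
#' @param points,kernel Training points and kernel, attached to the result so
#'   eigenfunctions can be evaluated anywhere ([evaluate_eigenfunctions()]).
#' @return A `koop_spectrum` with fields `values` (complex length-`K`),
#'   `coefficients` (`M x K`), `points`, `kernel`, `operator`, `epsilon`,
#'   `rank`.
#' @export
solve_general <- function(g2, g0, epsilon = NULL, n_eig = 10,
                          operator = c("schrodinger", "generator",
                                       "negative_generator"),
                          rank_tol = 1e-10, points = NULL, kernel = NULL) {
  operator <- match.arg(operator)
  stopifnot(is.matrix(g2), is.matrix(g0), all(dim(g2) == dim(g0)))
  epsilon <- epsilon %||% default_epsilon(g0)
  basis <- g0_basis(g0, rank_tol)
  cmat <- (crossprod(basis$q, g2) %*% basis$q) / (basis$lambda + epsilon)
  ee <- tryCatch(eigen(cmat),
                 error = function(e) stop_numerical(
                   "eigensolver failed on the regularized pencil: %s",
                   conditionMessage(e)))
  ord <- if (operator == "generator") {
    order(-Re(ee$values), Im(ee$values))
  } else {
    order(Re(ee$values), Im(ee$values))
  }
  take <- ord[seq_len(min(n_eig, length(ord)))]
  u <- basis$q %*% ee$vectors[, take, drop = FALSE]
  new_koop_spectrum(values = ee$values[take], coefficients = u, g0 = g0,
                    points = points, kernel = kernel, operator = operator,
                    epsilon = epsilon, rank = basis$rank)
}

#' Solve the symmetric (reversible) eigenvalue problem
#'
#' Solves \eqn{A u = \hat\lambda\,(G_0 G_0 + \epsilon I)\,u} with
#' \eqn{A = \tfrac12\sum_l G_1^{(l)\top} G_1^{(l)} + G_0\,\mathrm{diag}(W)\,G_0},
#' the Gram form of the symmetric estimator. The quadratic form expands as
#' \eqn{\tfrac1{2M}\sum_l \|G_1^{(l)} u\|^2}, which forces the transposed
#' factor on the left. Eigenvalues are real and returned ascending; they
#' estimate the spectrum of \eqn{-L + W} (nonnegative for \eqn{W \ge 0}).
#' Truncation acts on the squared Gram scale, matching the \eqn{G_0^2} mass
#' matrix.
#'
#' @param g1 List of matrices from [assemble_g1()].
#' @param g0 Gram matrix from [assemble_g0()].
#' @param w_samples Optional length-`M` multiplication term `W` (default 0).
#' @param epsilon Ridge for the mass matrix; default `1e-8 * mean(diag(G0))`.
#' @param n_eig Number of eigenpairs.
#' @param rank_tol Relative truncation threshold (applied to
#'   \eqn{(\lambda_i/\lambda_{max})^2}).
#' @param points,kernel Attached to the result for later evaluation.
#' @return A `koop_spectrum` with real `values`, `operator =
#'   "negative_generator"`.
#' @export
solve_symmetric <- function(g1, g0, w_samples = NULL, epsilon = NULL,
                            n_eig = 10, rank_tol = 1e-10, points = NULL,
                            kernel = NULL) {
  stopifnot(is.list(g1), is.matrix(g0))
  m <- nrow(g0)
  a <- matrix(0, m, m)
  for (g in g1) a <- a + 0.5 * crossprod(g)
  if (!is.null(w_samples) && any(w_samples != 0)) {
    stopifnot(length(w_samples) == m)
    a <- a + g0 %*% (w_samples * g0)
  }
  asym <- max(abs(a - t(a)))
  if (asym > 1e-8 * (max(abs(a)) + 1)) {
    stop_numerical("symmetric-estimator matrix A is asymmetric beyond tolerance (%g).",
                   asym)
  }
  a <- (a + t(a)) / 2
  epsilon <- epsilon %||% default_epsilon(g0)
  basis <- g0_basis(g0, rank_tol, squared = TRUE)
  bdiag <- basis$lambda^2 + epsilon
  ar <- crossprod(basis$q, a) %*% basis$q
  cmat <- ar / sqrt(bdiag)
  cmat <- t(t(cmat) / sqrt(bdiag))
  cmat <- (cmat + t(cmat)) / 2
  ee <- eigen(cmat, symmetric = TRUE)
  ord <- order(ee$values)
  take <- ord[seq_len(min(n_eig, length(ord)))]
  u <- basis$q %*% (ee$vectors[, take, drop = FALSE] / sqrt(bdiag))
  new_koop_spectrum(values = ee$values[take], coefficients = u, g0 = g0,
                    points = points, kernel = kernel,
                    operator = "negative_generator", epsilon = epsilon,
                    rank = basis$rank)
}

# Normalize coefficient columns to unit empirical mu-norm
# (u' G0 G0 u / M = 1, i.e. mean phi(x_m)^2 = 1) and fix the sign of real
# eigenvectors so the largest-magnitude entry is positive (reproducibility).
new_koop_spectrum <- function(values, coefficients, g0, points, kernel,
                              operator, epsilon, rank) {
  m <- nrow(g0)
  phi <- g0 %*% coefficients
  nrm <- sqrt(colMeans(Mod(phi)^2))
  nrm[nrm == 0] <- 1
  coefficients <- sweep(coefficients, 2, nrm, "/")
  real_cols <- apply(coefficients, 2, function(u) {
    max(Mod(Im(u))) <= 1e-10 * max(Mod(u), 1e-300)
  })
  if (any(real_cols)) {
    cr <- Re(coefficients[, real_cols, drop = FALSE])
    sgn <- apply(cr, 2, function(u) sign(u[which.max(abs(u))]))
    sgn[sgn == 0] <- 1
    coefficients[, real_cols] <- sweep(cr, 2, sgn, "*")
  }
  if (max(Mod(Im(coefficients))) == 0 && max(abs(Im(values))) == 0) {
    coefficients <- Re(coefficients)
    values <- Re(values)
  }
  structure(list(values = values, coefficients = coefficients,
                 points = if (!is.null(points)) as_points(points) else NULL,
                 kernel = kernel, operator = operator, epsilon = epsilon,
                 rank = rank, n = m),
            class = "koop_spectrum")
}

#' @export
print.koop_spectrum <- function(x, ...) {
  vals <- utils::head(x$values, 8)
  lab <- if (max(abs(Im(vals))) > 0) {
    sprintf("%.4g%+.2gi", Re(vals), Im(vals))
  } else {
    sprintf("%.4g", Re(vals))
  }
  cat(sprintf("<koop_spectrum> %s, %d eigenpairs from %d samples (rank %d)\n",
              x$operator, length(x$values), x$n, x$rank))
  cat("  leading eigenvalues:", paste(lab, collapse = ", "),
      if (length(x$values) > 8) "..." else "", "\n")
  invisible(x)
}

#' Evaluate estimated eigenfunctions at query points
#'
#' \eqn{\varphi_\ell(x) = \sum_m U_{m\ell}\, k(x_m, x)}, using the training
#' points and kernel stored in the spectral result.
#'
#' @param spectrum A `koop_spectrum` carrying `points` and `kernel`.
#' @param newdata Query points (`R x d` matrix or data frame).
#' @return `R x K` matrix (complex if the spectrum is complex).
#' @export
evaluate_eigenfunctions <- function(spectrum, newdata) {
  stopifnot(inherits(spectrum, "koop_spectrum"))
  if (is.null(spectrum$points) || is.null(spectrum$kernel)) {
    stop_config("spectrum carries no training points/kernel; re-solve with `points` and `kernel`.")
  }
  q <- as_points(newdata, spectrum$kernel$d)
  kqx <- kernel_matrix(spectrum$kernel, q, spectrum$points)
  kqx %*% spectrum$coefficients
}

#' Explicit-dictionary gEDMD reference
#'
#' Least-squares projection of the Koopman generator onto an explicit monomial
#' dictionary: \eqn{\hat L^\top = d\Phi_X \Phi_X^+}, where
#' \eqn{d\phi_n = \sum_i b_i \partial_i \phi_n + \tfrac12\sum_{ij} a_{ij}
#' \partial_i\partial_j \phi_n} with all derivatives computed analytically
#' from the exponents. Serves as the independent oracle for the kernel route:
#' when the kernel's feature space equals the dictionary span, the nonzero
#' eigenvalues of both routes agree to round-off.
#'
#' @param points `M x d` training points.
#' @param exponents `N x d` matrix of nonnegative integer monomial exponents
#'   (one dictionary function per row).
#' @param drift `M x d` matrix of drift samples `b(x_m)` (or a function).
#' @param a Diffusion matrix `a = sigma sigma'` (scalar, matrix, array or
#'   function, as in [coefficient_samples()]).
#' @return List with `values` (eigenvalues of \eqn{\hat L}, sorted by
#'   descending real part), `lhat` (the \eqn{N \times N} matrix),
#'   `condition` (condition number of \eqn{\Phi_X}) and `rank`.
#' @export
gedmd_reference <- function(points, exponents, drift, a) {
  x <- as_points(points)
  m <- nrow(x); d <- ncol(x)
  exponents <- as.matrix(exponents)
  if (ncol(exponents) != d || any(exponents < 0) ||
      any(exponents != round(exponents))) {
    stop_config("`exponents` must be an N x d matrix of nonnegative integers.")
  }
  b <- if (is.function(drift)) eval_field(drift, x, "vector") else {
    stopifnot(all(dim(drift) == c(m, d))); drift
  }
  a_arr <- coerce_a(a, x)
  mono <- function(expo) {
    out <- rep(1, m)
    for (i in seq_len(d)) if (expo[i] > 0) out <- out * x[, i]^expo[i]
    out
  }
  dmono <- function(expo, i) {
    if (expo[i] == 0) return(numeric(m))
    e2 <- expo; e2[i] <- e2[i] - 1L
    expo[i] * mono(e2)
  }
  d2mono <- function(expo, i, j) {
    if (expo[i] == 0) return(numeric(m))
    e2 <- expo; e2[i] <- e2[i] - 1L
    fac <- expo[i]
    if (e2[j] == 0) return(numeric(m))
    e3 <- e2; e3[j] <- e3[j] - 1L
    fac * e2[j] * mono(e3)
  }
  n <- nrow(exponents)
  phix <- matrix(0, n, m)
  dphix <- matrix(0, n, m)
  for (k in seq_len(n)) {
    expo <- exponents[k, ]
    phix[k, ] <- mono(expo)
    acc <- numeric(m)
    for (i in seq_len(d)) {
      acc <- acc + b[, i] * dmono(expo, i)
      for (j in seq_len(d)) {
        acc <- acc + 0.5 * a_arr[, i, j] * d2mono(expo, i, j)
      }
    }
    dphix[k, ] <- acc
  }
  sv <- svd(phix)
  tol <- max(dim(phix)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  if (!all(pos)) {
    message(sprintf("gEDMD dictionary is rank deficient (rank %d of %d); pseudo-inverse used, condition %.3g.",
                    sum(pos), length(sv$d), sv$d[1] / min(sv$d[sv$d > 0])))
  }
  pinv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  lhat_t <- dphix %*% pinv
  ev <- eigen(t(lhat_t), only.values = TRUE)$values
  list(values = ev[order(-Re(ev), Im(ev))], lhat = t(lhat_t),
       condition = sv$d[1] / min(sv$d[pos]),
       rank = sum(pos))
}
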