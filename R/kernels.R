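# Positive definite kernels with exact derivatives up to second order.
#
# Derivatives are always taken with respect to the FIRST kernel argument;
# this is the convention every estimator in the package relies on.

#' Gaussian (radial basis function) kernel
#'
#' Constructs a Gaussian kernel \eqn{k(x, x') = \exp(-\|x - x'\|^2 / 2\varsigma^2)}
#' on \eqn{R^d}. The Gaussian kernel is smooth, so all partial derivatives up
#' to second order (the orders needed by the generator estimators) exist and
#' are evaluated in closed form.
#'
#' @param bandwidth Positive bandwidth \eqn{\varsigma}.
#' @param d Dimension of the state space.
#' @return A `koop_kernel` object.
#' @examples
#' k <- gaussian_kernel(bandwidth = 0.5, d = 2)
#' kernel_eval(k, c(0, 0), c(1, 0))  # exp(-2)
#' @seealso [polynomial_kernel()], [custom_kernel()], [kernel_matrix()]
#' @export
gaussian_kernel <- function(bandwidth, d) {
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0) {
    stop_config("`bandwidth` must be a single positive number.")
  }
  d <- check_dimension(d)
  new_koop_kernel(family = "gaussian", d = d, params = list(bandwidth = bandwidth))
}

#' Polynomial kernel
#'
#' Constructs the polynomial kernel \eqn{k(x, x') = (c + x^\top x')^q}. Its
#' feature space is the span of monomials up to degree `q`, which makes it the
#' bridge between the kernel-based estimators and explicit-dictionary gEDMD
#' (see [gedmd_reference()]): with a finite known feature space the two routes
#' produce identical nonzero eigenvalues.
#'
#' @param degree Positive integer degree \eqn{q}.
#' @param offset Nonnegative offset \eqn{c} (default 0; `offset = 0`,
#'   `degree = 1` is the linear kernel).
#' @param d Dimension of the state space.
#' @return A `koop_kernel` object.
#' @export
polynomial_kernel <- function(degree, offset = 0, d) {
  if (!is.numeric(degree) || length(degree) != 1L || degree < 1 ||
      degree != round(degree)) {
    stop_config("`degree` must be a positive integer.")
  }
  if (!is.numeric(offset) || length(offset) != 1L || offset < 0) {
    stop_config("`offset` must be a nonnegative number.")
  }
  d <- check_dimension(d)
  new_koop_kernel(family = "polynomial", d = d,
                  params = list(degree = as.integer(degree), offset = offset))
}

#' User-defined kernel
#'
#' Registers a kernel supplied as an eval/grad/hessian trio of functions, each
#' taking two `d`-vectors (derivatives with respect to the first argument).
#' At registration the derivatives are validated against central finite
#' differences on random point pairs, so that a miscoded gradient fails fast
#' rather than corrupting Gram matrices downstream.
#'
#' @param eval Function `(x, y) ->` scalar kernel value.
#' @param grad Function `(x, y) ->` length-`d` gradient with respect to `x`.
#' @param hessian Function `(x, y) -> d x d` matrix of second partials in `x`.
#' @param d State-space dimension.
#' @param label Optional display name.
#' @param validate Check derivatives against finite differences (default TRUE).
#' @return A `koop_kernel` object.
#' @export
custom_kernel <- function(eval, grad, hessian, d, label = "custom",
                          validate = TRUE) {
  d <- check_dimension(d)
  stopifnot(is.function(eval), is.function(grad), is.function(hessian))
  k <- new_koop_kernel(family = "custom", d = d,
                       params = list(eval = eval, grad = grad,
                                     hessian = hessian, label = label))
  if (validate) {
    for (i in seq_len(5L)) {
      x <- stats::runif(d, -1, 1); y <- stats::runif(d, -1, 1)
      if (abs(eval(x, y) - eval(y, x)) > 1e-8 * (abs(eval(x, y)) + 1)) {
        stop_config("custom kernel is not symmetric at a random point pair.")
      }
      g_fd <- fd_gradient(function(z) eval(z, y), x)
      if (max(abs(grad(x, y) - g_fd)) > 1e-4 * (max(abs(g_fd)) + 1)) {
        stop_config("custom kernel gradient disagrees with finite differences.")
      }
      h_fd <- fd_hessian(function(z) eval(z, y), x)
      if (max(abs(hessian(x, y) - h_fd)) > 1e-3 * (max(abs(h_fd)) + 1)) {
        stop_config("custom kernel hessian disagrees with finite differences.")
      }
    }
  }
  k
}

new_koop_kernel <- function(family, d, params) {
  structure(list(family = family, d = d, params = params),
            class = "koop_kernel")
}

#' @export
print.koop_kernel <- function(x, ...) {
  desc <- switch(x$family,
    gaussian = sprintf("Gaussian kernel, bandwidth %g", x$params$bandwidth),
    polynomial = sprintf("Polynomial kernel, degree %d, offset %g",
                         x$params$degree, x$params$offset),
    custom = sprintf("Custom kernel '%s'", x$params$label))
  cat(sprintf("<koop_kernel> %s on R^%d\n", desc, x$d))
  invisible(x)
}

#' Multi-index for partial derivatives
#'
#' A multi-index \eqn{\alpha \in N_0^d} selects the partial derivative
#' \eqn{D^\alpha}. The estimators need at most second derivatives, so orders
#' \eqn{|\alpha| > 2} are rejected at construction rather than silently
#' falling back to numerics.
#'
#' @param alpha Vector of nonnegative integers, one per coordinate.
#' @return A `koop_multi_index` (integer vector with class attribute).
#' @export
multi_index <- function(alpha) {
  if (!is.numeric(alpha) || any(alpha < 0) || any(alpha != round(alpha))) {
    stop_config("`alpha` must be a vector of nonnegative integers.")
  }
  alpha <- as.integer(alpha)
  if (sum(alpha) > 2L) {
    stop_config(sprintf(
      "Derivative order |alpha| = %d is unsupported: only orders <= 2 are needed by the estimators.",
      sum(alpha)))
  }
  structure(alpha, class = "koop_multi_index")
}

as_multi_index <- function(alpha, d) {
  if (is.null(alpha)) alpha <- integer(d)
  if (!inherits(alpha, "koop_multi_index")) alpha <- multi_index(alpha)
  if (length(alpha) != d) {
    stop_config(sprintf("multi-index has length %d, expected %d.",
                        length(alpha), d))
  }
  alpha
}

check_dimension <- function(d) {
  if (!is.numeric(d) || length(d) != 1L || d < 1 || d != round(d)) {
    stop_config("`d` must be a positive integer dimension.")
  }
  as.integer(d)
}

check_vec <- function(x, d, what) {
  x <- as.numeric(x)
  if (length(x) != d) {
    stop_config(sprintf("`%s` has length %d but the kernel lives on R^%d.",
                        what, length(x), d))
  }
  x
}

#' Evaluate a kernel at a point pair
#'
#' @param kernel A `koop_kernel`.
#' @param x,y Points in \eqn{R^d} (the derivative-carrying slot is `x`).
#' @return Scalar \eqn{k(x, y)}.
#' @export
kernel_eval <- function(kernel, x, y) {
  x <- check_vec(x, kernel$d, "x"); y <- check_vec(y, kernel$d, "y")
  switch(kernel$family,
    gaussian = exp(-sum((x - y)^2) / (2 * kernel$params$bandwidth^2)),
    polynomial = (kernel$params$offset + sum(x * y))^kernel$params$degree,
    custom = kernel$params$eval(x, y))
}

#' Kernel gradient with respect to the first argument
#'
#' Closed forms: Gaussian \eqn{\nabla_1 k(x,y) = -(x-y) k(x,y)/\varsigma^2};
#' polynomial \eqn{\nabla_1 k(x,y) = q\, y\, (c + x^\top y)^{q-1}}.
#'
#' @inheritParams kernel_eval
#' @return Length-`d` numeric vector.
#' @export
kernel_grad <- function(kernel, x, y) {
  x <- check_vec(x, kernel$d, "x"); y <- check_vec(y, kernel$d, "y")
  switch(kernel$family,
    gaussian = {
      s2 <- kernel$params$bandwidth^2
      -(x - y) / s2 * exp(-sum((x - y)^2) / (2 * s2))
    },
    polynomial = {
      q <- kernel$params$degree
      q * y * (kernel$params$offset + sum(x * y))^(q - 1)
    },
    custom = as.numeric(kernel$params$grad(x, y)))
}

#' Kernel Hessian with respect to the first argument
#'
#' Closed forms: Gaussian
#' \eqn{\nabla^2_1 k = ((x-y)(x-y)^\top/\varsigma^4 - I/\varsigma^2) k};
#' polynomial \eqn{q(q-1)\, y y^\top (c + x^\top y)^{q-2}} (identically zero
#' for the linear kernel).
#'
#' @inheritParams kernel_eval
#' @return `d x d` numeric matrix.
#' @export
kernel_hessian <- function(kernel, x, y) {
  x <- check_vec(x, kernel$d, "x"); y <- check_vec(y, kernel$d, "y")
  d <- kernel$d
  switch(kernel$family,
    gaussian = {
      s2 <- kernel$params$bandwidth^2
      diff <- x - y
      (tcrossprod(diff) / s2^2 - diag(d) / s2) *
        exp(-sum(diff^2) / (2 * s2))
    },
    polynomial = {
      q <- kernel$params$degree
      if (q < 2) return(matrix(0, d, d))
      q * (q - 1) * tcrossprod(y) *
        (kernel$params$offset + sum(x * y))^(q - 2)
    },
    custom = {
      h <- kernel$params$hessian(x, y)
      matrix(as.numeric(h), d, d)
    })
}

#' Partial kernel derivative for a multi-index
#'
#' Returns \eqn{D^\alpha k(x, y)} with the derivative acting on the first
#' argument; consistent with [kernel_eval()], [kernel_grad()] and
#' [kernel_hessian()] for orders 0, 1 and 2 respectively.
#'
#' @inheritParams kernel_eval
#' @param alpha Multi-index (see [multi_index()]); orders above 2 error.
#' @return Scalar derivative value.
#' @export
kernel_partial <- function(kernel, alpha, x, y) {
  alpha <- as_multi_index(alpha, kernel$d)
  ord <- sum(alpha)
  if (ord == 0L) return(kernel_eval(kernel, x, y))
  if (ord == 1L) {
    i <- which(alpha == 1L)
    return(kernel_grad(kernel, x, y)[i])
  }
  ij <- rep(seq_along(alpha), alpha)
  kernel_hessian(kernel, x, y)[ij[1L], ij[2L]]
}

#' Pairwise (derivative) Gram matrix
#'
#' Vectorized assembly of the matrix with entries
#' \eqn{D^\alpha k(a_m, b_r)} for row points `a` and column points `b`; the
#' derivative acts on the first slot (the `a` points). With `alpha = NULL`
#' this is the plain Gram matrix.
#'
#' @param kernel A `koop_kernel`.
#' @param x `M x d` matrix (or data frame) of first-slot points.
#' @param y `R x d` matrix of second-slot points (default `x`).
#' @param alpha Optional multi-index of order at most 2.
#' @return `M x R` numeric matrix.
#' @export
kernel_matrix <- function(kernel, x, y = x, alpha = NULL) {
  x <- as_points(x, kernel$d); y <- as_points(y, kernel$d)
  alpha <- as_multi_index(alpha, kernel$d)
  ord <- sum(alpha)
  if (kernel$family == "gaussian") {
    s2 <- kernel$params$bandwidth^2
    d2 <- pairwise_sqdist(x, y)
    k <- exp(-d2 / (2 * s2))
    if (ord == 0L) return(k)
    if (ord == 1L) {
      i <- which(alpha == 1L)
      return(-outer(x[, i], y[, i], "-") / s2 * k)
    }
    ij <- rep(seq_along(alpha), alpha)
    di <- outer(x[, ij[1L]], y[, ij[1L]], "-")
    dj <- outer(x[, ij[2L]], y[, ij[2L]], "-")
    dd <- if (ij[1L] == ij[2L]) 1 / s2 else 0
    return((di * dj / s2^2 - dd) * k)
  }
  if (kernel$family == "polynomial") {
    q <- kernel$params$degree
    p <- kernel$params$offset + tcrossprod(x, y)
    if (ord == 0L) return(p^q)
    if (ord == 1L) {
      i <- which(alpha == 1L)
      return(q * matrix(y[, i], nrow(x), nrow(y), byrow = TRUE) * p^(q - 1))
    }
    if (q < 2) return(matrix(0, nrow(x), nrow(y)))
    ij <- rep(seq_along(alpha), alpha)
    yi <- matrix(y[, ij[1L]], nrow(x), nrow(y), byrow = TRUE)
    yj <- matrix(y[, ij[2L]], nrow(x), nrow(y), byrow = TRUE)
    return(q * (q - 1) * yi * yj * p^(q - 2))
  }
  # custom kernels: elementwise fallback
  out <- matrix(0, nrow(x), nrow(y))
  for (m in seq_len(nrow(x))) {
    for (r in seq_len(nrow(y))) {
      out[m, r] <- kernel_partial(kernel, alpha, x[m, ], y[r, ])
    }
  }
  out
}

pairwise_sqdist <- function(x, y) {
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  d2
}

# central finite differences, used for user-kernel validation and as the
# fallback for coefficient fields whose analytic derivatives are not supplied
fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

fd_hessian <- function(f, x, h = 1e-4) {
  d <- length(x)
  out <- matrix(0, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- numeric(d); ei[i] <- h
    out[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < d) for (j in seq((i + 1), d)) {
      ej <- numeric(d); ej[j] <- h
      out[i, j] <- out[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  out
}
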