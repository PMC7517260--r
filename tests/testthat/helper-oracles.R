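# Independent oracles used across the suite.

# Central finite-difference gradient/Hessian of k(., y) in its first slot.
fd_kernel_grad <- function(kernel, x, y, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (kernel_eval(kernel, x + e, y) - kernel_eval(kernel, x - e, y)) / (2 * h)
  }, numeric(1))
}

fd_kernel_hessian <- function(kernel, x, y, h = 1e-4) {
  d <- length(x)
  out <- matrix(0, d, d)
  f <- function(z) kernel_eval(kernel, z, y)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- numeric(d); ei[i] <- h
    out[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < d) for (j in (i + 1):d) {
      ej <- numeric(d); ej[j] <- h
      out[i, j] <- out[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  out
}

# Dense finite-difference discretization of -L = grad(V) . grad - beta^-1 Lap
# on an interval with reflecting boundaries; the eigenvalue oracle for 1-D
# reversible systems.
fd_negative_generator_1d <- function(grad_v, beta, lower, upper, n = 500) {
  x <- seq(lower, upper, length.out = n)
  h <- x[2] - x[1]
  vp <- grad_v(x)
  a <- matrix(0, n, n)
  for (i in 2:(n - 1)) {
    a[i, i - 1] <- -vp[i] / (2 * h) - 1 / (beta * h^2)
    a[i, i] <- 2 / (beta * h^2)
    a[i, i + 1] <- vp[i] / (2 * h) - 1 / (beta * h^2)
  }
  a[1, 1] <- 1 / (beta * h^2) - vp[1] / h
  a[1, 2] <- -1 / (beta * h^2) + vp[1] / h
  a[n, n] <- 1 / (beta * h^2) + vp[n] / h
  a[n, n - 1] <- -1 / (beta * h^2) - vp[n] / h
  sort(Re(eigen(a, only.values = TRUE)$values))
}

# Equilibrated OU samples by direct draw from the stationary law N(0, 1/(alpha beta)).
ou_stationary_sample <- function(m, alpha = 1, beta = 1, seed = 1) {
  withr::with_seed(seed, matrix(rnorm(m, 0, sqrt(1 / (alpha * beta))), ncol = 1))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
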