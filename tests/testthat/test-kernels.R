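test_that("closed-form kernel values match their formulas", {
  k <- gaussian_kernel(0.5, 2)
  expect_equal(kernel_eval(k, c(0, 0), c(1, 0)), exp(-2))
  expect_equal(kernel_eval(k, c(0.3, -1), c(0.3, -1)), 1)  # k(x, x) = 1

  lin <- polynomial_kernel(degree = 1, offset = 0, d = 3)
  x <- c(1, 2, 3); y <- c(-1, 0.5, 2)
  expect_equal(kernel_eval(lin, x, y), sum(x * y))

  g1 <- gaussian_kernel(1, 2)
  expect_equal(kernel_grad(g1, c(1, 0), c(0, 0)), c(-exp(-0.5), 0))
  expect_equal(kernel_grad(g1, c(0.7, -0.2), c(0.7, -0.2)), c(0, 0))
  expect_equal(kernel_hessian(g1, c(0.4, 0.4), c(0.4, 0.4)), -diag(2))
  expect_equal(kernel_hessian(polynomial_kernel(1, 0.5, 2), c(1, 2), c(3, 4)),
               matrix(0, 2, 2))
})

test_that("kernel derivatives agree with central finite differences", {
  kernels <- list(gaussian_kernel(0.8, 3),
                  polynomial_kernel(degree = 3, offset = 1.2, d = 3))
  withr::with_seed(42, {
    for (k in kernels) {
      for (rep in 1:10) {
        x <- runif(3, -1, 1); y <- runif(3, -1, 1)
        g <- kernel_grad(k, x, y)
        g_fd <- fd_kernel_grad(k, x, y)
        expect_lt(max(abs(g - g_fd)) / max(abs(g_fd)), 1e-6)
        h <- kernel_hessian(k, x, y)
        h_fd <- fd_kernel_hessian(k, x, y)
        expect_lt(max(abs(h - h_fd)) / max(abs(h_fd)), 1e-5)
      }
    }
  })
})

test_that("kernel_partial is consistent with eval/grad/hessian and bounds the order", {
  k <- gaussian_kernel(0.7, 3)
  x <- c(0.2, -0.4, 1); y <- c(1, 0.3, -0.5)
  expect_equal(kernel_partial(k, c(0, 0, 0), x, y), kernel_eval(k, x, y))
  expect_equal(kernel_partial(k, c(0, 1, 0), x, y), kernel_grad(k, x, y)[2])
  expect_equal(kernel_partial(k, c(1, 0, 1), x, y),
               kernel_hessian(k, x, y)[1, 3])
  expect_equal(kernel_partial(k, c(0, 2, 0), x, y),
               kernel_hessian(k, x, y)[2, 2])
  expect_error(multi_index(c(2, 1, 0)), class = "koop_config_error")
  expect_error(multi_index(c(-1, 0)), class = "koop_config_error")
  expect_error(kernel_eval(k, c(1, 2), y), class = "koop_config_error")
})

test_that("pairwise derivative matrices equal elementwise evaluation", {
  withr::with_seed(7, {
    a <- matrix(runif(10, -1, 1), 5, 2)
    b <- matrix(runif(8, -1, 1), 4, 2)
    for (k in list(gaussian_kernel(0.6, 2), polynomial_kernel(2, 1, 2))) {
      for (alpha in list(c(0, 0), c(1, 0), c(0, 1), c(2, 0), c(1, 1))) {
        km <- kernel_matrix(k, a, b, alpha)
        loop <- outer(seq_len(5), seq_len(4), Vectorize(function(m, r) {
          kernel_partial(k, alpha, a[m, ], b[r, ])
        }))
        expect_equal(km, loop, tolerance = 1e-12)
      }
    }
  })
})

test_that("Gram matrices are symmetric positive semidefinite", {
  withr::with_seed(3, {
    x <- matrix(rnorm(40), 20, 2)
    for (k in list(gaussian_kernel(1, 2), polynomial_kernel(2, 1, 2))) {
      g <- kernel_matrix(k, x, x)
      expect_equal(g, t(g), tolerance = 1e-12)
      ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), -1e-10 * max(abs(ev)))
    }
  })
})

test_that("the Gaussian kernel is translation invariant with opposite-slot gradients", {
  k <- gaussian_kernel(0.9, 2)
  withr::with_seed(5, {
    for (rep in 1:5) {
      x <- runif(2); y <- runif(2); t <- runif(2, -3, 3)
      expect_equal(kernel_eval(k, x + t, y + t), kernel_eval(k, x, y))
      # grad in the second argument via finite differences
      g2 <- vapply(1:2, function(i) {
        e <- numeric(2); e[i] <- 1e-6
        (kernel_eval(k, x, y + e) - kernel_eval(k, x, y - e)) / 2e-6
      }, numeric(1))
      expect_equal(kernel_grad(k, x, y), -g2, tolerance = 1e-6)
    }
  })
})

test_that("custom kernels are validated at registration", {
  s <- 0.8
  ok <- custom_kernel(
    eval = function(x, y) exp(-sum((x - y)^2) / (2 * s^2)),
    grad = function(x, y) -(x - y) / s^2 * exp(-sum((x - y)^2) / (2 * s^2)),
    hessian = function(x, y) {
      (tcrossprod(x - y) / s^4 - diag(2) / s^2) *
        exp(-sum((x - y)^2) / (2 * s^2))
    }, d = 2)
  ref <- gaussian_kernel(s, 2)
  x <- c(0.3, -0.1); y <- c(-0.5, 0.2)
  expect_equal(kernel_matrix(ok, rbind(x), rbind(y), c(1, 1)),
               kernel_matrix(ref, rbind(x), rbind(y), c(1, 1)),
               tolerance = 1e-10)
  expect_error(custom_kernel(
    eval = function(x, y) exp(-sum((x - y)^2)),
    grad = function(x, y) (x - y) * exp(-sum((x - y)^2)),  # wrong sign
    hessian = function(x, y) diag(2), d = 2),
    class = "koop_config_error")
})
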