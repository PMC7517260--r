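test_that("G0 is the standard Gram matrix", {
  k <- gaussian_kernel(1, 2)
  expect_equal(assemble_g0(rbind(c(0.5, -1)), k), matrix(1, 1, 1))
  withr::with_seed(4, {
    x <- matrix(rnorm(40), 20, 2)
    g0 <- assemble_g0(x, k)
    expect_equal(g0, t(g0))
    ev <- eigen(g0, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10 * max(ev))
    expect_equal(g0[3, 7], kernel_eval(k, x[3, ], x[7, ]))
  })
})

test_that("G1 matches its definition and is skew-symmetric for constant diffusion", {
  k <- gaussian_kernel(0.7, 2)
  withr::with_seed(5, {
    x <- matrix(rnorm(24), 12, 2)
    g1 <- assemble_g1(x, k, diag(2))   # sigma = I
    expect_length(g1, 2)
    for (l in 1:2) {
      expect_equal(diag(g1[[l]]), rep(0, 12))        # grad k(x, x) = 0
      expect_equal(g1[[l]], -t(g1[[l]]), tolerance = 1e-12)
      loop <- outer(1:12, 1:12, Vectorize(function(m, r) {
        sum(diag(2)[, l] * kernel_grad(k, x[m, ], x[r, ]))
      }))
      expect_equal(g1[[l]], loop, tolerance = 1e-12)
    }
    # non-trivial constant sigma
    sig <- matrix(c(1, 0.3, -0.2, 0.8), 2, 2)
    g1s <- assemble_g1(x, k, sig)
    loop <- outer(1:12, 1:12, Vectorize(function(m, r) {
      sum(sig[, 2] * kernel_grad(k, x[m, ], x[r, ]))
    }))
    expect_equal(g1s[[2]], loop, tolerance = 1e-12)
  })
})

test_that("G2 reduces correctly in degenerate cases and matches an analytic oracle", {
  k <- gaussian_kernel(0.9, 1)
  withr::with_seed(6, {
    x <- matrix(rnorm(8), ncol = 1)
    g0 <- assemble_g0(x, k)
    zero <- assemble_g2(x, k, coefficient_samples(x, a = 0))
    expect_equal(zero, matrix(0, 8, 8))
    mult1 <- assemble_g2(x, k, coefficient_samples(x, a = 0, w = 1))
    expect_equal(mult1, g0, tolerance = 1e-12)

    # OU generator applied in the first slot: L k = b dk + (1/2) a d2k
    alpha <- 1.3; beta <- 2
    model <- ou_model(alpha, beta)
    co <- operator_coefficients(model, x, operator = "generator")
    g2 <- assemble_g2(x, k, co)
    s <- 0.9
    oracle <- outer(1:8, 1:8, Vectorize(function(m, r) {
      xm <- x[m, 1]; xr <- x[r, 1]
      kk <- exp(-(xm - xr)^2 / (2 * s^2))
      dk <- -(xm - xr) / s^2 * kk
      d2k <- ((xm - xr)^2 / s^4 - 1 / s^2) * kk
      (-alpha * xm) * dk + (1 / beta) * 2 * 0.5 * d2k
    }))
    expect_equal(g2, oracle, tolerance = 1e-12)
  })
})

test_that("the identity pencil has unit eigenvalues", {
  k <- gaussian_kernel(1, 1)
  withr::with_seed(8, x <- matrix(rnorm(30), ncol = 1))
  g0 <- assemble_g0(x, k)
  res <- solve_general(g0, g0, epsilon = 0, n_eig = 5, points = x, kernel = k)
  expect_equal(Re(res$values), rep(1, 5), tolerance = 1e-8)
})

test_that("the general estimator recovers the OU spectrum and Hermite eigenfunctions", {
  model <- ou_model(alpha = 1, beta = 1)
  traj <- euler_maruyama(model, x0 = 0, n_steps = 6e4, dt = 5e-3,
                         burn_in = 4e3, stride = 112, seed = 11)
  x <- as_points(traj)
  expect_equal(nrow(x), 500)
  k <- gaussian_kernel(1, 1)
  g0 <- assemble_g0(x, k)
  g2 <- assemble_g2(x, k, operator_coefficients(model, x, "generator"))
  res <- solve_general(g2, g0, n_eig = 4, operator = "generator",
                       points = x, kernel = k)
  ev <- Re(res$values)
  expect_lt(abs(ev[1]), 0.05)
  expect_lt(abs(ev[2] + 1) / 1, 0.05)
  expect_lt(abs(ev[3] + 2) / 2, 0.05)

  phi <- Re(evaluate_eigenfunctions(res, x))
  # phi_0 is near-constant: coefficient of variation below 5%
  expect_lt(sd(phi[, 1]) / abs(mean(phi[, 1])), 0.05)
  for (l in 1:3) {
    he <- hermite_probabilists(sqrt(1 * 1) * x[, 1], l)
    expect_gt(abs(cor(phi[, l + 1], he)), 0.99)
  }
})

test_that("the symmetric estimator matrix is PSD and degenerate inputs give zero", {
  k <- gaussian_kernel(0.8, 1)
  withr::with_seed(9, x <- matrix(rnorm(40), ncol = 1))
  g0 <- assemble_g0(x, k)
  zero <- list(matrix(0, 40, 40))
  res0 <- solve_symmetric(zero, g0, n_eig = 5, points = x, kernel = k)
  expect_equal(Re(res0$values), rep(0, 5), tolerance = 1e-10)

  g1 <- assemble_g1(x, k, sqrt(2))
  a <- 0.5 * crossprod(g1[[1]])
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10 * max(ev))
})

test_that("the reversible estimator matches a finite-difference operator oracle", {
  # 1-D double well V = (x^2-1)^2 at beta = 1
  model <- langevin_model(potential = function(x) (x[, 1]^2 - 1)^2,
                          grad_potential = function(x) 4 * x * (x^2 - 1),
                          beta = 1, d = 1, vectorized = TRUE)
  traj <- euler_maruyama(model, x0 = 1, n_steps = 4.1e5, dt = 1e-3,
                         burn_in = 1e4, stride = 200, seed = 3)
  x <- as_points(traj)
  k <- gaussian_kernel(0.5, 1)
  g0 <- assemble_g0(x, k)
  g1 <- assemble_g1(x, k, attr(traj, "sigma"))
  res <- solve_symmetric(g1, g0, n_eig = 3, points = x, kernel = k)
  exact <- fd_negative_generator_1d(function(x) 4 * x * (x^2 - 1), beta = 1,
                                    lower = -2.5, upper = 2.5, n = 500)
  expect_lt(abs(Re(res$values)[1]), 0.05)
  for (l in 2:3) {
    expect_lt(abs(Re(res$values)[l] - exact[l]) / exact[l], 0.10)
  }
})

test_that("eigenfunction evaluation at the training points is the representation identity", {
  k <- gaussian_kernel(1, 2)
  withr::with_seed(10, x <- matrix(rnorm(30), 15, 2))
  g0 <- assemble_g0(x, k)
  res <- solve_general(g0, g0, epsilon = 0, n_eig = 3, points = x, kernel = k)
  expect_equal(evaluate_eigenfunctions(res, x), g0 %*% res$coefficients,
               tolerance = 1e-10)
})

test_that("explicit-dictionary gEDMD is exact on generator-invariant dictionaries", {
  withr::with_seed(12, x <- matrix(rnorm(100), ncol = 1))
  b <- -1.5 * x                                 # OU alpha = 1.5
  only1 <- gedmd_reference(x, exponents = matrix(0, 1, 1), drift = b, a = 2)
  expect_equal(Re(only1$values), 0, tolerance = 1e-12)

  dict <- matrix(c(0, 1, 2), ncol = 1)          # {1, x, x^2} is L-invariant
  ref <- gedmd_reference(x, dict, drift = b, a = 2)
  expect_equal(sort(Re(ref$values)), c(-3, -1.5, 0), tolerance = 1e-10)
  expect_equal(max(abs(Im(ref$values))), 0, tolerance = 1e-10)
})

test_that("the polynomial-kernel route reproduces gEDMD when the feature spaces agree", {
  withr::with_seed(13, x <- ou_stationary_sample(100, alpha = 1, beta = 1, seed = 13))
  model <- ou_model(1, 1)
  ref <- gedmd_reference(x, matrix(c(0, 1, 2), ncol = 1),
                         drift = koopkernel:::drift_at(model, x), a = 2)
  k <- polynomial_kernel(degree = 2, offset = 1, d = 1)
  g0 <- assemble_g0(x, k)
  g2 <- assemble_g2(x, k, operator_coefficients(model, x, "generator"))
  res <- solve_general(g2, g0, epsilon = 0, n_eig = 3, operator = "generator",
                       points = x, kernel = k)
  expect_equal(sort(Re(res$values)), sort(Re(ref$values)), tolerance = 1e-8)
})
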