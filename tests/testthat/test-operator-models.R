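test_that("the Langevin construction wires drift, diffusion and (V, beta) together", {
  m <- langevin_model(potential = function(x) 0.5 * x[, 1]^2,
                      grad_potential = function(x) x,
                      beta = 1, d = 1, vectorized = TRUE)
  x <- matrix(c(-2, 0, 1.5), ncol = 1)
  expect_equal(koopkernel:::drift_at(m, x), -x)
  expect_equal(m$a_const, matrix(2, 1, 1))
  expect_error(langevin_model(function(x) x^2, function(x) 2 * x,
                              beta = -1, d = 1),
               class = "koop_config_error")

  qw <- quadruple_well_model(beta = 4)
  mins <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  expect_equal(koopkernel:::drift_at(qw, mins), matrix(0, 4, 2))
  expect_equal(koopkernel:::potential_at(qw, rbind(c(0, 0))), 2)
  expect_equal(koopkernel:::potential_at(qw, rbind(c(1, 1))), 0)
  # four symmetric minima under coordinate sign flips
  expect_equal(koopkernel:::potential_at(qw, mins), rep(0, 4))
})

test_that("reversible gradient systems have zero stationary flow", {
  qw <- quadruple_well_model(beta = 2)
  j <- stationary_flow(qw)
  withr::with_seed(1, {
    x <- matrix(runif(200, -2, 2), 100, 2)
    expect_lt(max(abs(j(x))), 1e-12)
  })
})

test_that("stationary flow reproduces hand-computed fields", {
  # b = 0, a = 2I, F = |x|^2/2  ->  J = -x
  m0 <- drift_diffusion_model(drift = function(x) 0 * x,
                              diffusion = diag(sqrt(2), 2), d = 2,
                              vectorized = TRUE)
  j0 <- stationary_flow(m0, grad_F = function(x) x)
  x <- rbind(c(1, -2), c(0.5, 0.25))
  expect_equal(j0(x), -x)

  # pure rotation b = (-x2, x1), same a and F: J = -x + (x2, -x1)
  mrot <- drift_diffusion_model(drift = function(x) cbind(-x[, 2], x[, 1]),
                                diffusion = diag(sqrt(2), 2), d = 2,
                                vectorized = TRUE)
  jrot <- stationary_flow(mrot, grad_F = function(x) x)
  expect_equal(jrot(x), -x + cbind(x[, 2], -x[, 1]))
})

test_that("the generator-to-Schrodinger potential annihilates exp(-F/2)", {
  wflat <- schrodinger_from_generator(F_fun = function(x) 1.3,
                                      grad_F = function(x) c(0, 0),
                                      a = diag(2), d = 2)
  expect_equal(wflat(rbind(c(0.4, -2), c(1, 1))), c(0, 0))

  # OU: F = alpha beta x^2 / 2, a = 2/beta; closed-form W and FD annihilation
  alpha <- 1.7; beta <- 2.5
  w <- schrodinger_from_generator(
    F_fun = function(x) 0.5 * alpha * beta * sum(x^2),
    grad_F = function(x) alpha * beta * x,
    hess_F = function(x) matrix(alpha * beta, 1, 1),
    a = 2 / beta, d = 1)
  xs <- matrix(seq(-3, 3, length.out = 50), ncol = 1)
  expect_equal(w(xs), alpha^2 * beta / 4 * xs[, 1]^2 - alpha / 2,
               tolerance = 1e-12)
  res <- annihilation_residual(
    F_fun = function(x) 0.5 * alpha * beta * sum(x^2),
    W_fun = w, a = 2 / beta, grid = xs)
  expect_lt(max(abs(res)), 1e-4)
})

test_that("a ground state induces the dual drift-diffusion process", {
  gs <- qho_ground_state()          # eta = x^2/2, E0 = 1/2
  m <- sde_from_ground_state(gs)
  x <- matrix(c(-1, 0.5, 2), ncol = 1)
  expect_equal(koopkernel:::drift_at(m, x), -x)      # OU with alpha = hbar omega = 1
  expect_equal(m$beta, 2)                            # beta^-1 = hbar^2 / 2m
  expect_equal(m$a_const, matrix(1, 1, 1))

  gh <- hydrogen_ground_state()
  mh <- sde_from_ground_state(gh)
  xh <- rbind(c(3, 0, 4))
  expect_equal(koopkernel:::drift_at(mh, xh), -xh / 5)  # -x/|x|
  expect_error(sde_from_ground_state(gs, hbar = -1),
               class = "koop_config_error")

  # constant eta: zero drift, pure diffusion a = (hbar^2/m) I
  g0 <- ground_state(eta = function(x) rep(1, nrow(x)),
                     grad_eta = function(x) 0 * x, energy = 0, d = 2,
                     vectorized = TRUE)
  m0 <- sde_from_ground_state(g0, hbar = 2, mass = 1)
  expect_equal(koopkernel:::drift_at(m0, rbind(c(1, 2))), matrix(0, 1, 2))
  expect_equal(m0$a_const, diag(4, 2))
})

test_that("round trip ground state -> SDE -> Schrodinger potential recovers W - E0", {
  # QHO: eta = x^2/2; F = 2 eta; dual a = hbar^2/m = 1
  gs <- qho_ground_state()
  w <- schrodinger_from_generator(
    F_fun = function(x) sum(x^2), grad_F = function(x) 2 * x,
    hess_F = function(x) matrix(2, 1, 1), a = 1, d = 1)
  xs <- matrix(seq(-2, 2, length.out = 21), ncol = 1)
  # recovered potential equals W_qho - E0 = x^2/2 - 1/2
  expect_equal(w(xs), 0.5 * xs[, 1]^2 - 0.5, tolerance = 1e-12)
})

test_that("spectrum_transform maps generator eigenvalues to energies and wavefunctions", {
  # synthetic generator spectrum for the OU dual of the QHO
  kern <- gaussian_kernel(1, 1)
  pts <- matrix(seq(-2, 2, length.out = 9), ncol = 1)
  g0 <- assemble_g0(pts, kern)
  fake <- koopkernel:::new_koop_spectrum(
    values = c(0, -1, -2), coefficients = diag(9)[, 1:3], g0 = g0,
    points = pts, kernel = kern, operator = "generator", epsilon = 0,
    rank = 9)
  wf <- spectrum_transform(fake, qho_ground_state())
  expect_equal(wf$energies, c(0.5, 1.5, 2.5))   # E = E0 - lambda

  psi <- evaluate_wavefunctions(wf, pts, normalize = FALSE)
  phi <- Re(evaluate_eigenfunctions(fake, pts))
  expect_equal(psi, exp(-pts[, 1]^2 / 2) * phi)
  psin <- evaluate_wavefunctions(wf, pts)
  expect_equal(colMeans(psin^2), rep(1, 3))
})

test_that("the first-order coefficient equals -b for generators and 0 for Hamiltonians", {
  qw <- quadruple_well_model(beta = 3)
  c1 <- first_order_coefficient(qw)
  withr::with_seed(2, {
    x <- matrix(runif(60, -2, 2), 30, 2)
    expect_equal(c1(x), -koopkernel:::drift_at(qw, x))
  })
  ch <- first_order_coefficient(qho_model())
  expect_equal(ch(matrix(c(1, 2), ncol = 1)), matrix(0, 2, 1))

  # elliptic form with constant a and F: c1 = J + a grad(F)/2
  ell <- elliptic_operator_model(a = diag(2, 2), d = 2,
                                 flow = function(x) c(-x[2], x[1]),
                                 grad_F = function(x) x)
  ce <- ell |> first_order_coefficient()
  xx <- rbind(c(1, 2))
  expect_equal(ce(xx), cbind(1 * 1 + -2, 1 * 2 + 1))
})
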