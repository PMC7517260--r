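test_that("the KDE potential gradient has its closed forms and invariances", {
  one <- kde_fit(matrix(c(0, 0), 1, 2), bandwidth = 0.5)
  q <- rbind(c(1, -2), c(0.2, 0.4))
  expect_equal(kde_grad_logdensity(one, q), q / 0.25)  # single Gaussian: x / sigma^2

  withr::with_seed(14, x <- matrix(rnorm(4000), ncol = 1))
  kde <- kde_fit(x, bandwidth = 0.25)
  # consistency on standard normal data: grad U(x) ~ x / (1 + sigma^2)
  grid <- matrix(seq(-2, 2, length.out = 17), ncol = 1)
  gu <- kde_grad_logdensity(kde, grid)
  slope <- coef(lm(gu[, 1] ~ grid[, 1]))[2]
  expect_lt(abs(slope - 1 / (1 + 0.25^2)), 0.1)
  expect_lt(max(abs(gu[, 1] - grid[, 1] / (1 + 0.25^2))), 0.35)
  # densities are strictly positive and finite even far in the tails
  far <- matrix(c(-40, 40), ncol = 1)
  expect_true(all(is.finite(kde_density(kde, far, log = TRUE))))
  expect_true(all(kde_density(kde, grid) > 0))
  # the gradient of -log rho is invariant to the normalization constant by
  # construction: it only uses weight ratios
  expect_equal(kde_grad_logdensity(kde, grid),
               kde_grad_logdensity(kde_fit(x, 0.25), grid))
})

test_that("KDE-drift embedding of a Gaussian blob recovers the OU structure", {
  withr::with_seed(15, x <- matrix(rnorm(1200), ncol = 2))
  emb <- manifold_embedding(x, kernel = gaussian_kernel(1, 2), n_coords = 3,
                            method = "kde_drift", kde_bandwidth = 0.3,
                            rank_tol = 1e-6)
  # leading generator eigenvalue ~ 0, next pair ~ -1/(1 + sigma_kde^2)
  expect_lt(abs(emb$spectrum$values[1]), 0.1)
  # first retained coordinate is a linear function of position
  fit <- summary(lm(emb$coordinates$phi1 ~ x[, 1] + x[, 2]))
  expect_gt(sqrt(fit$r.squared), 0.95)
})

test_that("reversible and KDE-drift embeddings expose the same leading subspace on a blob", {
  withr::with_seed(16, x <- matrix(rnorm(2000), ncol = 2))
  er <- manifold_embedding(x, kernel = gaussian_kernel(1, 2), n_coords = 2,
                           method = "reversible", rank_tol = 1e-5)
  fit1 <- summary(lm(er$coordinates$phi1 ~ x[, 1] + x[, 2]))
  expect_gt(sqrt(fit1$r.squared), 0.95)
  expect_gt(er$values[1], -2)  # slow linear mode, eigenvalue near -1
  expect_lt(er$values[1], -0.5)
})

test_that("metastable analysis recovers the four wells and is seed-stable", {
  model <- quadruple_well_model(beta = 1)
  traj <- euler_maruyama(model, x0 = c(1, 1), n_steps = 6.1e5, dt = 1e-3,
                         burn_in = 1e4, stride = 400, seed = 21)
  dec <- metastable_analysis(traj, kernel = gaussian_kernel(0.5, 2),
                             n_eig = 8, seed = 1)
  expect_equal(dec$n_dominant, 4)
  expect_equal(dec$n_sets, 4)
  x <- as_points(traj)
  quadrant <- paste(sign(x[, 1]), sign(x[, 2]))
  expect_gt(adjusted_rand(dec$labels, quadrant), 0.95)

  # label invariance under k-means seed changes (up to permutation)
  for (s in 2:4) {
    dec_s <- metastable_analysis(traj, kernel = gaussian_kernel(0.5, 2),
                                 n_eig = 8, seed = s)
    expect_gt(adjusted_rand(dec$labels, dec_s$labels), 0.99)
  }

  # invariance under eigenfunction sign flips: clustering the flipped
  # coordinates produces the same partition
  phi <- Re(assemble_g0(x, gaussian_kernel(0.5, 2)) %*%
              dec$spectrum$coefficients[, 1:4])
  km <- withr::with_seed(1, kmeans(-phi, centers = 4, nstart = 25))
  expect_gt(adjusted_rand(dec$labels, km$cluster), 0.99)

  one <- metastable_analysis(traj, kernel = gaussian_kernel(0.5, 2),
                             n_eig = 8, n_sets = 1, seed = 1)
  expect_equal(length(unique(one$labels)), 1)
  expect_error(metastable_analysis(traj, n_eig = 3, n_sets = 5),
               class = "koop_config_error")
})

test_that("the spectral-gap detector finds the dominant block", {
  expect_equal(spectral_gap_index(c(0.009, 0.400, 1.011, 1.55, 5.9, 6.5, 7, 8)),
               4)
  expect_equal(spectral_gap_index(c(1e-6, 0.5, 5, 6, 7, 8)), 2)
  expect_equal(spectral_gap_index(c(0, 0.2, 0.21, 0.22, 0.25, 4, 5, 6)), 5)
})

test_that("direct and SDE-dual routes agree on the harmonic oscillator", {
  pts <- sample_uniform_box(-5, 5, 100, d = 1, seed = 17)
  direct <- schrodinger_direct(pts, qho_model(), kernel = gaussian_kernel(1, 1),
                               n_eig = 6)
  e_direct <- Re(direct$values)[1:4]
  expect_lt(max(abs(e_direct - qho_energies(0:3)) / qho_energies(0:3)), 0.05)

  x <- ou_stationary_sample(500, alpha = 1, beta = 2, seed = 18)
  wf <- schrodinger_via_sde(qho_ground_state(), x,
                            kernel = gaussian_kernel(1, 1), n_eig = 6)
  e_dual <- wf$energies[1:4]
  expect_lt(max(abs(e_dual - qho_energies(0:3)) / qho_energies(0:3)), 0.05)
  expect_lt(max(abs(e_dual - e_direct) / e_direct), 0.05)

  # wavefunctions carry the Hermite-Gaussian shapes: psi_1 ~ x exp(-x^2/2)
  grid <- matrix(seq(-3, 3, length.out = 61), ncol = 1)
  psi <- evaluate_wavefunctions(wf, grid)
  ref <- grid[, 1] * exp(-grid[, 1]^2 / 2)
  expect_gt(abs(cor(psi[, 2], ref)), 0.99)
  # densities |psi|^2 are nonnegative by construction
  expect_true(all(psi^2 >= 0))
})

test_that("singular potential samples are rejected with a warning", {
  pts <- rbind(c(0, 0, 0), as_points(sample_uniform_ball(5, 60, 3, seed = 19)))
  expect_warning(
    spec <- schrodinger_direct(pts, hydrogen_model(),
                               kernel = gaussian_kernel(2, 3), n_eig = 3),
    regexp = "rejected")
  expect_equal(spec$n, 60)
})
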