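test_that("gabor bank has uniform orientations, equal norms, and 90-degree rotational structure", {
  A <- build_gabor_bank(4, 8)
  expect_equal(attr(A, "orientations"), c(-90, -45, 0, 45))
  expect_equal(dim(A), c(64, 4))

  A8 <- build_gabor_bank(8, 16)
  norms <- sqrt(colSums(A8^2))
  expect_lt(max(norms) - min(norms), 1e-6)

  # column k + 4 is the 90-degree rotation of column k as a pixel image
  for (k in 1:4) {
    M1 <- matrix(A8[, k], 16, 16)
    M2 <- matrix(A8[, k + 4], 16, 16)
    expect_lt(max(abs(M2 - rotate90_image(M1))), 1e-9)
  }

  expect_error(build_gabor_bank(4, 8, list(env_sigma = 0)), "invalid")
})

test_that("prior covariance is circulant, positive definite, and matches direct kernel evaluation", {
  orientations <- -90 + 180 * (0:5) / 6
  C <- build_prior_cov(orientations, list(width = 30))
  expect_equal(C, t(C))
  expect_true(all(eigen(C, symmetric = TRUE, only.values = TRUE)$values > 0))
  # circulant: every row is a rotation of the first
  for (i in 2:6)
    expect_equal(C[i, ], C[1, c((6 - i + 2):6, 1:(6 - i + 1))],
                 tolerance = 1e-12)
  # direct periodized-kernel oracle for each entry
  oracle <- function(a, b, width) {
    dd <- abs(a - b) %% 180; dd <- min(dd, 180 - dd)
    num <- sum(exp(-(dd + 180 * (-2:2))^2 / (2 * width^2)))
    den <- sum(exp(-(180 * (-2:2))^2 / (2 * width^2)))
    num / den
  }
  for (i in 1:6) for (j in 1:6) {
    expected <- oracle(orientations[i], orientations[j], 30) +
      (i == j) * 1e-9
    expect_equal(C[i, j], expected, tolerance = 1e-12)
  }
  # width -> 0 gives (near) identity
  C0 <- build_prior_cov(orientations, list(width = 1e-3))
  expect_lt(max(abs(C0 - diag(6))), 1e-8)
})

test_that("forward samples are seeded-reproducible and have the right marginal covariance", {
  m <- small_gsm()
  s1 <- sample_patch(m, z = 1.5, rng_seed = 7)
  s2 <- sample_patch(m, z = 1.5, rng_seed = 7)
  expect_identical(s1, s2)

  expect_error(sample_patch(m, z = -1), "nonnegative")

  # z = 0: pure pixel noise
  xs0 <- sapply(1:2000, function(i) sample_patch(m, z = 0, rng_seed = i)$x)
  expect_equal(mean(apply(xs0, 1, var)), m$sigma_x2, tolerance = 0.05)

  # z = 1: cov(x) ~ A C A^T + sigma_x2 I
  xs <- sapply(1:4000, function(i) sample_patch(m, z = 1, rng_seed = 10000 + i)$x)
  emp <- cov(t(xs))
  expected <- m$A %*% m$C %*% t(m$A) + m$sigma_x2 * diag(m$n_pixels)
  expect_lt(max(abs(emp - expected)), 6 * max(abs(expected)) / sqrt(4000) * 3)
})

test_that("conditional posterior matches the 1D conjugate closed form and dense quadrature", {
  # 1-latent GSM with C = 4, A = 10 (per pixel), sigma_x2 = 100
  m1 <- gsm_model(A = matrix(10, 1, 1), C = matrix(4, 1, 1), sigma_x2 = 100)
  ps <- posterior_given_z(m1, x = 10, z = 1)
  expect_equal(ps$mean, 0.8, tolerance = 1e-12)
  expect_equal(ps$cov[1, 1], 0.8, tolerance = 1e-12)
  q <- quad_posterior_1d(A = 10, C = 4, s2 = 100, x = 10, z = 1)
  expect_equal(ps$mean, q$mean, tolerance = 1e-8)
  expect_equal(ps$cov[1, 1], q$var, tolerance = 1e-7)

  # 3-latent instance against the joint-grid quadrature oracle
  m <- small_gsm()
  s <- sample_patch(m, z = 1.2, rng_seed = 3)
  ps3 <- posterior_given_z(m, s$x, 1.2)
  q3 <- quad_posterior_joint(m$A, m$C, m$sigma_x2, s$x, 1.2)
  expect_lt(rel_err(ps3$mean, q3$mean), 1e-6)
  expect_lt(rel_err(ps3$cov, q3$cov), 1e-6)
  expect_equal(ps3$sd^2, diag(ps3$cov), tolerance = 1e-12)
})

test_that("zero-contrast posterior equals the prior bitwise", {
  m <- small_gsm()
  x <- sample_patch(m, z = 2, rng_seed = 1)$x
  p0 <- posterior_given_z(m, x, 0)
  expect_identical(p0$cov, m$C)
  expect_identical(p0$mean, rep(0, m$n_latents))
  pm0 <- posterior_moments(m, x, z_grid = 0)
  expect_identical(pm0$cov, m$C)
  expect_true(all(pm0$mean == 0))
})

test_that("contrast posterior normalizes, matches direct evaluation, and ranks evidence sensibly", {
  m <- small_gsm()
  s <- sample_patch(m, z = 3, rng_seed = 11)
  zg <- default_z_grid(60)
  cp <- contrast_posterior(m, s$x, zg)
  expect_equal(sum(cp$weights), 1, tolerance = 1e-12)
  direct <- contrast_weights_direct(m$A, m$C, m$sigma_x2,
                                    m$contrast_prior["shape"],
                                    m$contrast_prior["scale"], s$x, zg)
  expect_lt(max(abs(cp$weights - direct)), 1e-8)

  # zero patch concentrates the posterior at low contrast
  cp0 <- contrast_posterior(m, rep(0, m$n_pixels), zg)
  ez0 <- sum(cp0$weights * zg)
  ez3 <- sum(cp$weights * zg)
  expect_lt(ez0, 1)
  expect_gt(ez3, ez0)

  # the same patch scaled down 10x implies lower contrast
  cp_small <- contrast_posterior(m, s$x / 10, zg)
  expect_gt(ez3, sum(cp_small$weights * zg))
})

test_that("marginalized moments: degenerate grid, grid refinement, and total-variance bound", {
  m <- small_gsm()
  s <- sample_patch(m, z = 1, rng_seed = 21)
  pg <- posterior_given_z(m, s$x, 0.8)
  pm1 <- posterior_moments(m, s$x, z_grid = 0.8)
  expect_equal(pm1$mean, pg$mean, tolerance = 1e-12)
  expect_equal(pm1$cov, pg$cov, tolerance = 1e-12)

  coarse <- posterior_moments(m, s$x, default_z_grid(50))
  fine <- posterior_moments(m, s$x, default_z_grid(500))
  expect_lt(rel_err(coarse$mean, fine$mean), 1e-3)
  expect_lt(rel_err(coarse$cov, fine$cov), 1e-3)

  # mixture variance >= smallest conditional variance, elementwise
  zg <- default_z_grid(50)
  cond_var <- sapply(zg, function(z) diag(posterior_given_z(m, s$x, z)$cov))
  expect_true(all(diag(coarse$cov) >= apply(cond_var, 1, min) - 1e-12))
})

test_that("hypoprior scales the prior and inflates posterior mean and uncertainty", {
  m <- small_gsm()
  expect_identical(apply_hypoprior(m, 1)$C, m$C)
  expect_error(apply_hypoprior(m, 0), "positive")
  expect_warning(apply_hypoprior(m, 0.8), "narrows")

  mh <- apply_hypoprior(m, 1.5)
  expect_equal(sqrt(diag(mh$C)), sqrt(1.5) * sqrt(diag(m$C)), tolerance = 1e-12)

  # ordering holds for every bank stimulus at z > 0
  bank <- make_bank(m, orientations = c(-45, 0, 45),
                    contrast_levels = c(0.5, 1, 2))
  for (i in seq_len(nrow(bank$patches))) {
    x <- bank$patches[i, ]
    pt <- posterior_moments(m, x)
    ph <- posterior_moments(mh, x)
    expect_gt(mean(ph$sd), mean(pt$sd))
    expect_gt(mean(ph$mean), mean(pt$mean))
  }
})

test_that("1D toy curves match the conjugate closed form and its limits", {
  tab <- toy1d_curves(z_values = c(0, 1, 50))
  expect_equal(tab$mean_true[1], 0)
  expect_equal(tab$sd_true[1], 2)
  expect_equal(tab$sd_hypo[1], sqrt(6), tolerance = 1e-12)
  expect_equal(tab$mean_true[2], 0.8, tolerance = 1e-12)
  expect_equal(tab$sd_true[2], sqrt(0.8), tolerance = 1e-12)
  expect_equal(tab$mean_hypo[2], 6 / 7, tolerance = 1e-12)
  expect_equal(tab$sd_hypo[2], sqrt(6 / 7), tolerance = 1e-12)

  # quadrature cross-check at z = 1
  q <- quad_posterior_1d(A = 10, C = 4, s2 = 100, x = 10, z = 1)
  expect_equal(tab$mean_true[2], q$mean, tolerance = 1e-8)
  qh <- quad_posterior_1d(A = 10, C = 6, s2 = 100, x = 10, z = 1)
  expect_equal(tab$mean_hypo[2], qh$mean, tolerance = 1e-8)

  # likelihood dominance: both means approach x_obs / (z A); curves converge
  expect_equal(tab$mean_true[3], 10 / (50 * 10), tolerance = 1e-3)
  expect_lt(abs(tab$mean_hypo[3] - tab$mean_true[3]), 1e-5)

  # sd_true strictly decreasing in z
  tab2 <- toy1d_curves(z_values = seq(0, 4, by = 0.25))
  expect_true(all(diff(tab2$sd_true) < 0))
})
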