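# small, comfortably stable ring used across these tests
test_net <- function(n_pairs = 8, ...) {
  build_ring(n_pairs, ring_defaults(
    J = c(EE = 1.2, EI = 1.0, IE = 1.5, II = 0.6),
    width = c(EE = 40, EI = 60, IE = 40, II = 60),
    noise = list(sd_E = 0.5, sd_I = 0.5, tau_ms = 5),
    ff = list(baseline_E = 2, baseline_I = 1.5),
    ...))
}

test_that("ring construction obeys Dale's principle and circulant kernel structure", {
  net <- test_net()
  N <- net$n_pairs
  expect_true(all(net$W[, 1:N] >= 0))
  expect_true(all(net$W[, N + 1:N] <= 0))

  # E->E block entries match direct kernel evaluation (row-normalized)
  d <- outer(net$orientations, net$orientations, orientation_distance)
  K <- exp(-d^2 / (2 * 40^2))
  for (kk in c(-2, -1, 1, 2)) K <- K + exp(-(d + 180 * kk)^2 / (2 * 40^2))
  K <- K / sum(exp(-(180 * (-2:2))^2 / (2 * 40^2)))
  K <- K / sum(K[1, ])
  expect_equal(net$W[1:N, 1:N], 1.2 * K, tolerance = 1e-12)

  # circulant under pair rotation: spectrum of the EE block matches the
  # Fourier transform of its first row
  ee <- net$W[1:N, 1:N]
  ev <- sort(Re(eigen(ee, only.values = TRUE)$values))
  ft <- sort(Re(fft(ee[1, ])))
  expect_equal(ev, ft, tolerance = 1e-9)

  # delta-width kernels leave only within-pair connections
  net0 <- build_ring(8, ring_defaults(
    J = c(EE = 1, EI = 1, IE = 1, II = 1),
    width = c(EE = 1e-3, EI = 1e-3, IE = 1e-3, II = 1e-3)))
  offdiag <- net0$W[1:8, 1:8]; diag(offdiag) <- 0
  expect_lt(max(abs(offdiag)), 1e-10)

  expect_error(build_ring(8, ring_defaults(J = c(EE = -1))), "Dale")
})

test_that("feedforward drive: baseline at zero patch, monotone in stimulus scale, tuned argmax", {
  m <- gsm_model(n_latents = 8, patch_side = 8)
  net <- build_ring(8, ring_defaults(ff = list(gain_E = 0.5, gain_I = 0.1,
                                               baseline_E = 2, baseline_I = 1)),
                    ff_filters = m$A)
  h0 <- feedforward_input(net, rep(0, 64))
  expect_equal(h0, c(rep(2, 8), rep(1, 8)))

  bank <- make_bank(m, orientations = 0, contrast_levels = c(1, 2))
  h1 <- feedforward_input(net, bank$patches[1, ])
  h2 <- feedforward_input(net, bank$patches[2, ])
  expect_true(all(h2 >= h1))

  # strongest E drive at the pair preferring the stimulus orientation
  ctr <- which.min(orientation_distance(net$orientations, 0))
  expect_equal(which.max(h2[1:8]), ctr)

  expect_error(feedforward_input(net, rep(0, 10)), "match")
})

test_that("noise-free simulation decays exponentially and converges to the fixed point", {
  # pure leak: W = 0, h = 0
  net <- test_net()
  net$W[] <- 0
  u0 <- rep(c(2, -1), each = 8)
  traj <- simulate_ring(net, h = rep(0, 16), duration = 60, dt = 0.1,
                        record_every = 1, u0 = u0, noise = FALSE)
  i40 <- which(traj$t == 40)
  expect_equal(traj$u[i40, ], u0 * exp(-40 / net$tau), tolerance = 1e-2)

  # generic stable net relaxes to the root-solver fixed point
  net2 <- test_net()
  h <- baseline_input(net2) + 0.5
  fp <- fixed_point(net2, h)
  expect_lt(attr(fp, "residual"), 1e-10)
  traj2 <- simulate_ring(net2, h, duration = 2000, dt = 0.1,
                         record_every = 10, noise = FALSE)
  expect_lt(max(abs(traj2$u[nrow(traj2$u), ] - fp)), 1e-6)
})

test_that("trajectories are seed-reproducible and rate-consistent", {
  net <- test_net()
  h <- baseline_input(net)
  t1 <- simulate_ring(net, h, duration = 500, seed = 5)
  t2 <- simulate_ring(net, h, duration = 500, seed = 5)
  expect_identical(t1$u, t2$u)
  t3 <- simulate_ring(net, h, duration = 500, seed = 6)
  expect_false(identical(t1$u, t3$u))

  expect_equal(t1$r, net$k * pmax(t1$u, 0)^net$m, tolerance = 1e-12)
  expect_true(all(t1$r >= 0))
  expect_true(all(diff(t1$t) == 1))
})

test_that("linear-regime stationary covariance matches the Lyapunov solution", {
  # m = 1, no rectification: the (u, eta) system is linear; its stationary
  # covariance solves the joint Lyapunov equation
  net <- build_ring(4, ring_defaults(
    J = c(EE = 0.8, EI = 0.9, IE = 1.0, II = 0.5),
    width = c(EE = 40, EI = 60, IE = 40, II = 60),
    m = 1, k = 0.5,
    noise = list(sd_E = 0.4, sd_I = 0.4, tau_ms = 5),
    ff = list(baseline_E = 1, baseline_I = 0.8)))
  n <- 8
  h <- baseline_input(net)
  Tinv <- diag(1 / net$tau)
  A_u <- Tinv %*% (-diag(n) + net$k * net$W)
  A_joint <- rbind(cbind(A_u, Tinv),
                   cbind(matrix(0, n, n), -diag(n) / net$noise$tau_ms))
  Q <- matrix(0, 2 * n, 2 * n)
  Q[n + 1:n, n + 1:n] <- 2 * net$noise$Sigma / net$noise$tau_ms
  X <- lyapunov_cov(A_joint, Q)
  sd_expected <- sqrt(diag(X)[1:n])

  traj <- simulate_ring(net, h, duration = 60000, dt = 0.25, seed = 17,
                        record_every = 5, rectify = FALSE)
  keep <- traj$t > 500
  sd_emp <- apply(traj$u[keep, ], 2, sd)
  # Monte-Carlo SE of an SD estimate from correlated samples: conservative
  # effective sample size from the ~tau_E autocorrelation time
  n_eff <- sum(keep) * 5 / (3 * net$tau[1])
  se <- sd_expected / sqrt(2 * n_eff)
  expect_true(all(abs(sd_emp - sd_expected) < 3 * se + 0.02 * sd_expected))
})

test_that("fixed_point solves the scalar self-coupled cell against bisection", {
  net <- test_net(n_pairs = 4)
  net$W[] <- 0
  net$W[1, 1] <- 0.5
  h <- rep(0.5, 8); h[1] <- 1.0
  fp <- fixed_point(net, h)
  # scalar equation u = h + w k u^m for cell 1, solved by bisection on the
  # bracket containing the stable (lower) root
  f <- function(u) -u + 1.0 + 0.5 * net$k * pmax(u, 0)^net$m
  lo <- 0; hi <- 3
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(fp[1], (lo + hi) / 2, tolerance = 1e-8)
  expect_equal(fp[2], 0.5, tolerance = 1e-10)
  expect_lt(attr(fp, "residual"), 1e-10)

  net0 <- test_net(n_pairs = 4)
  net0$W[] <- 0
  expect_equal(as.numeric(fixed_point(net0, rep(0, 8))), rep(0, 8))
})

test_that("dt refinement leaves stationary means within Monte-Carlo error", {
  net <- test_net()
  h <- baseline_input(net)
  m1 <- stationary_moments(simulate_ring(net, h, 8000, dt = 0.2, seed = 3,
                                         record_every = 2),
                           burn_in = 500, thin = 10)
  m2 <- stationary_moments(simulate_ring(net, h, 8000, dt = 0.1, seed = 3,
                                         record_every = 2),
                           burn_in = 500, thin = 10)
  se <- apply(simulate_ring(net, h, 8000, dt = 0.2, seed = 4,
                            record_every = 2)$u, 2, sd) /
    sqrt(8000 / (3 * net$tau[1]))
  expect_true(all(abs(m1$mean_u - m2$mean_u) < 4 * se + 0.02))
})

test_that("simulation guards reject bad settings and detect divergence", {
  net <- test_net()
  expect_error(simulate_ring(net, baseline_input(net), 100, dt = 5), "dt")
  expect_error(simulate_ring(net, baseline_input(net), 100, dt = 0.2,
                             record_every = 0.3), "multiple")
  # runaway excitation reports the divergence time instead of NaNs
  bad <- net
  bad$W[1:8, 1:8] <- 60
  expect_error(simulate_ring(bad, baseline_input(bad) + 10, 2000, seed = 1),
               "unstable")
})

test_that("ring networks serialize to JSON and back", {
  m <- gsm_model(n_latents = 8, patch_side = 8)
  net <- build_ring(8, ring_defaults(ff = list(gain_E = 0.5)),
                    ff_filters = m$A)
  net2 <- scale_inhibition(net, 0.1)
  path <- tempfile(fileext = ".json")
  write_ring(net2, path)
  back <- read_ring(path)
  expect_equal(back$W, net2$W, tolerance = 1e-12)
  expect_equal(back$W_ff, net2$W_ff, tolerance = 1e-12)
  expect_equal(back$tau, net2$tau)
})
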