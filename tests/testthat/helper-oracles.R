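# Independent oracles used across the test suite. These deliberately avoid
# the package's own linear-algebra shortcuts: posteriors are computed by
# dense-grid quadrature over the latent space, rotations by explicit pixel
# remapping, stationary covariances by solving the Lyapunov equation with a
# Kronecker-product linear solve.

# Posterior mean/cov of y given (x, z) by Riemann quadrature on a regular
# grid covering +/- hw prior SDs in every latent dimension (d <= 3).
quad_posterior_joint <- function(A, C, s2, x, z, n = 81, hw = 10) {
  d <- nrow(C)
  stopifnot(d <= 3)
  sds <- sqrt(diag(C))
  axes <- lapply(seq_len(d), function(i) seq(-hw * sds[i], hw * sds[i],
                                             length.out = n))
  Y <- as.matrix(expand.grid(axes))
  Cinv <- solve(C)
  log_prior <- -0.5 * rowSums((Y %*% Cinv) * Y)
  XB <- Y %*% t(A) * z                      # predicted patch per grid point
  log_lik <- -0.5 * rowSums(sweep(XB, 2, as.numeric(x))^2) / s2
  lw <- log_prior + log_lik
  w <- exp(lw - max(lw)); w <- w / sum(w)
  mu <- colSums(Y * w)
  Yc <- sweep(Y, 2, mu)
  cov <- t(Yc) %*% (Yc * w)
  list(mean = mu, cov = cov)
}

# 1D special case with its own code path (scalar quadrature).
quad_posterior_1d <- function(A, C, s2, x, z, n = 20001, hw = 12) {
  y <- seq(-hw * sqrt(C), hw * sqrt(C), length.out = n)
  lw <- -0.5 * y^2 / C - 0.5 * (x - z * A * y)^2 / s2
  w <- exp(lw - max(lw)); w <- w / sum(w)
  mu <- sum(y * w)
  list(mean = mu, var = sum((y - mu)^2 * w))
}

# Rotate a square pixel matrix by 90 degrees counterclockwise in the
# coordinate convention of the Gabor renderer (x right, y up).
rotate90_image <- function(M) {
  p <- nrow(M)
  out <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) out[i, j] <- M[j, p + 1 - i]
  out
}

# Mean firing rate E[k max(u,0)^m] for u ~ N(mu, sd^2), by adaptive
# quadrature.
rate_mean_gauss <- function(mu, sd, k, m) {
  stats::integrate(function(u) k * pmax(u, 0)^m * stats::dnorm(u, mu, sd),
                   lower = 0, upper = mu + 12 * sd, rel.tol = 1e-10)$value
}

# Stationary covariance of dx = A x dt + dW with diffusion Q:
# solves A X + X A^T + Q = 0 by the Kronecker vectorization.
lyapunov_cov <- function(A, Q) {
  n <- nrow(A)
  K <- kronecker(diag(n), A) + kronecker(A, diag(n))
  matrix(solve(K, -as.numeric(Q)), n, n)
}

# Evidence-based contrast weights by direct dense evaluation (full
# covariance per grid point; no eigen shortcut).
contrast_weights_direct <- function(A, C, s2, shape, scale, x, z_grid) {
  npix <- nrow(A)
  M <- A %*% C %*% t(A)
  lw <- vapply(z_grid, function(z) {
    S <- z^2 * M + s2 * diag(npix)
    ch <- chol(S)
    -sum(log(diag(ch))) - 0.5 * sum(backsolve(ch, x, transpose = TRUE)^2) +
      stats::dgamma(z, shape = shape, scale = scale, log = TRUE)
  }, numeric(1))
  w <- exp(lw - max(lw))
  w / sum(w)
}

# small GSM instance shared by several tests
small_gsm <- function(n_latents = 3, patch_side = 6, sigma_x2 = 0.25,
                      width = 35) {
  gsm_model(n_latents = n_latents, patch_side = patch_side,
            sigma_x2 = sigma_x2, kernel_params = list(width = width))
}

# relative sup-norm discrepancy
rel_err <- function(a, b) max(abs(a - b)) / max(abs(b))
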