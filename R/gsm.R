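#' Build an oriented Gabor feature bank
#'
#' Renders `n_latents` Gabor filters on a `patch_side` x `patch_side` pixel
#' grid, at orientations uniformly spaced on \[-90, 90) (0 degrees =
#' vertical). All columns are rotations of a single template: an isotropic
#' Gaussian envelope times a cosine carrier. Each rendered filter is
#' mean-corrected and scaled to unit norm, so all column norms are exactly
#' equal.
#'
#' @param n_latents number of filters (>= 2).
#' @param patch_side pixels per side (>= 4).
#' @param gabor_params list with `env_sigma` (envelope SD, pixels),
#'   `wavelength` (carrier period, pixels), `phase` (radians). Defaults:
#'   `patch_side/5`, `patch_side/2`, 0.
#' @return `patch_side^2` x `n_latents` matrix; column k is the filter at
#'   orientation `-90 + 180*(k-1)/n_latents` degrees.
#' @export
build_gabor_bank <- function(n_latents, patch_side, gabor_params = list()) {
  stopifnot(n_latents >= 2, patch_side >= 4)
  gp <- utils::modifyList(
    list(env_sigma = patch_side / 5, wavelength = patch_side / 2, phase = 0),
    gabor_params)
  if (gp$env_sigma <= 0 || gp$wavelength <= 0)
    stop("invalid gabor_params: envelope sigma and wavelength must be > 0")
  half <- (patch_side - 1) / 2
  xs <- seq(-half, half, length.out = patch_side)
  gx <- matrix(rep(xs, each = patch_side), patch_side)  # column index -> x
  gy <- matrix(rep(rev(xs), patch_side), patch_side)    # row index    -> y
  orientations <- -90 + 180 * (seq_len(n_latents) - 1) / n_latents
  A <- sapply(orientations, function(th) {
    phi <- th * pi / 180
    carrier <- cos(2 * pi / gp$wavelength *
                     (gx * cos(phi) + gy * sin(phi)) + gp$phase)
    g <- exp(-(gx^2 + gy^2) / (2 * gp$env_sigma^2)) * carrier
    g <- g - mean(g)
    as.numeric(g) / sqrt(sum(g^2))
  })
  attr(A, "orientations") <- orientations
  attr(A, "patch_side") <- patch_side
  A
}

#' Stationary prior covariance on the orientation ring
#'
#' Gaussian kernel of the wrapped orientation distance (period 180
#' degrees), periodized over the circle so the matrix is symmetric,
#' circulant in the orientation index, and positive definite; a small
#' diagonal jitter guards the Cholesky factorization.
#'
#' @param orientations uniformly spaced orientations, degrees.
#' @param kernel_params list with `variance` (marginal variance, default 1),
#'   `width` (correlation width, degrees, default 25), `jitter` (default
#'   1e-9).
#' @return covariance matrix.
#' @export
build_prior_cov <- function(orientations, kernel_params = list()) {
  kp <- utils::modifyList(list(variance = 1, width = 25, jitter = 1e-9),
                          kernel_params)
  stopifnot(kp$variance > 0, kp$width > 0)
  C <- kp$variance * ring_kernel_matrix(orientations, kp$width) +
    kp$jitter * diag(length(orientations))
  ev_min <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0)
    stop("prior covariance is not positive definite (smallest eigenvalue ",
         format(ev_min), ")")
  C
}

#' Construct a Gaussian scale mixture model
#'
#' The generative model of image patches: `x = z * A %*% y + noise`, with
#' feature coefficients `y ~ N(0, C)`, a global contrast scalar
#' `z ~ Gamma(shape, scale)`, and isotropic pixel noise of variance
#' `sigma_x2`. Columns of `A` are oriented Gabor features; `C` is a
#' rotation-symmetric covariance on the orientation ring.
#'
#' @param n_latents number of latent features (default 32).
#' @param patch_side patch side in pixels (default 16).
#' @param sigma_x2 pixel noise variance (default 0.25).
#' @param gabor_params see [build_gabor_bank()].
#' @param kernel_params see [build_prior_cov()].
#' @param contrast_prior `c(shape, scale)` of the gamma prior on z
#'   (default `c(2, 1)`).
#' @param A,C optional explicit feature matrix / prior covariance
#'   (overriding the built ones); used for small bespoke instances.
#' @return object of class `gsm_model`.
#' @export
gsm_model <- function(n_latents = 32, patch_side = 16, sigma_x2 = 0.25,
                      gabor_params = list(), kernel_params = list(),
                      contrast_prior = c(shape = 2, scale = 1),
                      A = NULL, C = NULL) {
  stopifnot(sigma_x2 > 0, contrast_prior[1] > 0, contrast_prior[2] > 0)
  if (is.null(A)) A <- build_gabor_bank(n_latents, patch_side, gabor_params)
  orientations <- attr(A, "orientations")
  if (is.null(orientations))
    orientations <- -90 + 180 * (seq_len(ncol(A)) - 1) / ncol(A)
  if (is.null(C)) C <- build_prior_cov(orientations, kernel_params)
  if (ncol(A) != nrow(C)) stop("A and C dimensions disagree")
  if (max(abs(C - t(C))) > 1e-8) stop("C must be symmetric")
  if (length(orientations) != ncol(A))
    stop("number of orientations must equal number of latents")
  # eigendecomposition of the signal covariance A C A^T, reused by the
  # contrast posterior; rank <= n_latents so only the leading part is kept
  M <- A %*% C %*% t(A)
  ev <- eigen(M, symmetric = TRUE)
  r <- sum(ev$values > max(ev$values) * 1e-12)
  model <- list(A = A, C = C, sigma_x2 = sigma_x2,
                contrast_prior = c(shape = unname(contrast_prior[1]),
                                   scale = unname(contrast_prior[2])),
                orientations = orientations,
                patch_side = attr(A, "patch_side") %||% NA_integer_,
                n_latents = ncol(A), n_pixels = nrow(A),
                signal_evd = list(values = pmax(ev$values[seq_len(r)], 0),
                                  vectors = ev$vectors[, seq_len(r), drop = FALSE]),
                hypoprior_alpha = 1)
  class(model) <- "gsm_model"
  model
}

#' @export
print.gsm_model <- function(x, ...) {
  cat("gsm_model:", x$n_latents, "latents,", x$n_pixels, "pixels, sigma_x2 =",
      x$sigma_x2, "\n")
  cat("  contrast prior: Gamma(shape =", x$contrast_prior["shape"],
      ", scale =", x$contrast_prior["scale"], ")\n")
  if (x$hypoprior_alpha != 1)
    cat("  hypoprior: prior covariance scaled by alpha =",
        x$hypoprior_alpha, "\n")
  invisible(x)
}

#' Sample an image patch from the generative model
#'
#' Draws `y ~ N(0, C)`, optionally `z` from the gamma contrast prior, and
#' returns `x = z * A y + eps` with `eps ~ N(0, sigma_x2 I)`, together with
#' the latents used (for testing and for training records).
#'
#' @param model `gsm_model`.
#' @param z fixed nonnegative contrast, or `"from-prior"`.
#' @param rng_seed integer seed; fixed seed gives a bit-identical draw.
#' @return list with `x` (pixel vector), `y`, `z`.
#' @export
sample_patch <- function(model, z = "from-prior", rng_seed = 1) {
  set.seed(rng_seed)
  if (identical(z, "from-prior")) {
    z <- stats::rgamma(1, shape = model$contrast_prior["shape"],
                       scale = model$contrast_prior["scale"])
  } else {
    stopifnot(is.numeric(z), length(z) == 1)
    if (z < 0) stop("contrast z must be nonnegative")
  }
  Lc <- t(chol(model$C))
  y <- drop(Lc %*% stats::rnorm(model$n_latents))
  x <- z * drop(model$A %*% y) +
    sqrt(model$sigma_x2) * stats::rnorm(model$n_pixels)
  list(x = x, y = y, z = unname(z))
}

#' Posterior over feature coefficients at a known contrast
#'
#' Conditional-Gaussian posterior `p(y | x, z)`:
#' `cov = (C^-1 + z^2 A^T A / sigma_x2)^-1`,
#' `mean = cov %*% (z A^T x / sigma_x2)`. At `z = 0` the posterior equals
#' the prior exactly (mean 0, covariance `C`, bitwise).
#'
#' @param model `gsm_model`.
#' @param x pixel vector.
#' @param z nonnegative contrast.
#' @param stimulus_id optional identifier.
#' @return object of class `posterior_summary` with `mean`, `cov`, `sd`.
#' @export
posterior_given_z <- function(model, x, z, stimulus_id = NA) {
  x <- as.numeric(x)
  if (length(x) != model$n_pixels)
    stop("x has length ", length(x), ", expected ", model$n_pixels)
  stopifnot(z >= 0)
  if (z == 0) {
    out <- list(mean = rep(0, model$n_latents), cov = model$C,
                sd = sqrt(diag(model$C)), stimulus_id = stimulus_id,
                contrast_grid_used = 0)
    class(out) <- "posterior_summary"
    return(out)
  }
  Cinv <- tryCatch(chol2inv(chol(model$C)),
                   error = function(e) stop("prior covariance C is singular"))
  prec <- Cinv + (z^2 / model$sigma_x2) * crossprod(model$A)
  cov <- chol2inv(chol(prec))
  cov <- (cov + t(cov)) / 2
  mean <- drop(cov %*% (z * crossprod(model$A, x) / model$sigma_x2))
  out <- list(mean = mean, cov = cov, sd = sqrt(pmax(diag(cov), 0)),
              stimulus_id = stimulus_id, contrast_grid_used = z)
  class(out) <- "posterior_summary"
  out
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("posterior_summary over", length(x$mean), "latents\n")
  cat("  mean in [", round(min(x$mean), 3), ",", round(max(x$mean), 3),
      "], sd in [", round(min(x$sd), 3), ",", round(max(x$sd), 3), "]\n")
  invisible(x)
}

#' Default contrast integration grid
#'
#' 80 log-spaced points on `[1e-3, 12]`, covering the effective support of
#' the default Gamma(2, 1) contrast prior.
#'
#' @param n number of points.
#' @param lo,hi grid limits.
#' @return increasing positive vector.
#' @export
default_z_grid <- function(n = 80, lo = 1e-3, hi = 12) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Posterior weights over the contrast variable
#'
#' Evaluates `w(z) proportional to N(x; 0, z^2 A C A^T + sigma_x2 I) *
#' gamma_pdf(z)` on a grid, in log space, normalized to sum to one. Uses
#' the cached eigendecomposition of `A C A^T` so each grid point costs
#' O(rank).
#'
#' @param model `gsm_model`.
#' @param x pixel vector.
#' @param z_grid increasing nonnegative contrast grid.
#' @return named list: `weights` (sums to 1), `log_evidence` (unnormalized
#'   log posterior over the grid), `z_grid`.
#' @export
contrast_posterior <- function(model, x, z_grid = default_z_grid()) {
  x <- as.numeric(x)
  stopifnot(length(x) == model$n_pixels, all(diff(z_grid) > 0),
            all(z_grid >= 0))
  d <- model$signal_evd$values
  U <- model$signal_evd$vectors
  s2 <- model$sigma_x2
  proj <- drop(crossprod(U, x))
  resid2 <- sum(x^2) - sum(proj^2)
  n_null <- model$n_pixels - length(d)
  lw <- vapply(z_grid, function(z) {
    den <- z^2 * d + s2
    -0.5 * (sum(log(den)) + n_null * log(s2) +
              sum(proj^2 / den) + resid2 / s2) +
      stats::dgamma(z, shape = model$contrast_prior["shape"],
                    scale = model$contrast_prior["scale"], log = TRUE)
  }, numeric(1))
  if (!any(is.finite(lw))) {
    if (length(z_grid) == 1)   # degenerate one-point grid: weight is 1
      return(list(weights = 1, log_evidence = lw, z_grid = z_grid))
    stop("all contrast-posterior weights underflow; extend or refine z_grid")
  }
  m <- max(lw[is.finite(lw)])
  w <- exp(lw - m)
  w[!is.finite(w)] <- 0
  list(weights = w / sum(w), log_evidence = lw, z_grid = z_grid)
}

#' Contrast-marginalized posterior moments
#'
#' Mixture of conditional posteriors over the contrast grid: with weights
#' `w(z)` from [contrast_posterior()],
#' `mean = sum w(z) mu(z)` and
#' `cov = sum w(z) (Sigma(z) + mu(z) mu(z)^T) - mean mean^T`
#' (law of total variance).
#'
#' @param model `gsm_model`.
#' @param x pixel vector.
#' @param z_grid contrast grid (default [default_z_grid()]).
#' @param stimulus_id optional identifier.
#' @return `posterior_summary` with `contrast_grid_used = z_grid`.
#' @export
posterior_moments <- function(model, x, z_grid = default_z_grid(),
                              stimulus_id = NA) {
  x <- as.numeric(x)
  cp <- contrast_posterior(model, x, z_grid)
  w <- cp$weights
  n <- model$n_latents
  s2 <- model$sigma_x2
  Cinv <- chol2inv(chol(model$C))
  AtA <- crossprod(model$A)
  Atx <- drop(crossprod(model$A, x))
  mean_acc <- numeric(n)
  M2 <- matrix(0, n, n)
  for (i in seq_along(z_grid)) {
    if (w[i] < 1e-15) next
    z <- z_grid[i]
    if (z == 0) {
      mu <- numeric(n); Sg <- model$C
    } else {
      Sg <- chol2inv(chol(Cinv + (z^2 / s2) * AtA))
      mu <- drop(Sg %*% (z * Atx / s2))
    }
    mean_acc <- mean_acc + w[i] * mu
    M2 <- M2 + w[i] * (Sg + tcrossprod(mu))
  }
  cov <- M2 - tcrossprod(mean_acc)
  cov <- (cov + t(cov)) / 2
  out <- list(mean = mean_acc, cov = cov, sd = sqrt(pmax(diag(cov), 0)),
              stimulus_id = stimulus_id, contrast_grid_used = z_grid)
  class(out) <- "posterior_summary"
  out
}

#' Apply a hypoprior (broadened prior) to the model
#'
#' Scales the prior covariance, `C <- alpha * C`, leaving every other field
#' untouched. `alpha > 1` widens the prior (the hypoprior regime);
#' `alpha < 1` is allowed for exploration but flagged with a warning.
#'
#' @param model `gsm_model`.
#' @param alpha positive scale factor (reference value 1.5).
#' @return modified `gsm_model`.
#' @export
apply_hypoprior <- function(model, alpha = 1.5) {
  if (alpha <= 0) stop("alpha must be positive")
  if (alpha < 1)
    warning("alpha < 1 narrows the prior (hyperprior regime, exploratory)")
  model$C <- alpha * model$C
  model$signal_evd$values <- alpha * model$signal_evd$values
  model$hypoprior_alpha <- model$hypoprior_alpha * alpha
  model
}

#' Closed-form posterior curves for the 1D conjugate toy model
#'
#' One-dimensional model with known contrast (contrast indexes the
#' likelihood precision): posterior precision `1/C' + z^2 A^2 / sigma_x2`
#' with `C'` either the true prior variance `C` or the hypoprior variance
#' `alpha * C`; posterior mean `(z A x_obs / sigma_x2) / precision`.
#'
#' @param C prior variance (> 0, reference value 4).
#' @param A scalar feature weight (reference value 10).
#' @param sigma_x2 observation noise variance (reference value 100).
#' @param alpha hypoprior scale (reference value 1.5).
#' @param x_obs observed scalar.
#' @param z_values contrast values.
#' @return data.frame with columns `z`, `mean_true`, `sd_true`, `mean_hypo`,
#'   `sd_hypo`.
#' @export
toy1d_curves <- function(C = 4, A = 10, sigma_x2 = 100, alpha = 1.5,
                         x_obs = 10, z_values = seq(0, 4, by = 0.1)) {
  stopifnot(C > 0, sigma_x2 > 0, alpha > 0, all(z_values >= 0))
  one <- function(Cp) {
    prec <- 1 / Cp + z_values^2 * A^2 / sigma_x2
    list(mean = (z_values * A * x_obs / sigma_x2) / prec,
         sd = sqrt(1 / prec))
  }
  tr <- one(C); hy <- one(alpha * C)
  data.frame(z = z_values, mean_true = tr$mean, sd_true = tr$sd,
             mean_hypo = hy$mean, sd_hypo = hy$sd)
}

#' Posterior summary as a data frame
#'
#' Long-format view (one row per latent) for CSV export.
#'
#' @param ps `posterior_summary`.
#' @param orientations per-latent orientations, degrees.
#' @return data.frame with `stimulus_id`, `orientation_deg`, `mean`, `sd`.
#' @export
posterior_to_df <- function(ps, orientations) {
  data.frame(stimulus_id = ps$stimulus_id,
             orientation_deg = orientations,
             mean = ps$mean, sd = ps$sd)
}
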