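#' Deterministic stimulus bank of oriented patches
#'
#' For every (orientation, contrast) combination, renders a patch
#' `z * A %*% y_star` where `y_star` is a positive wrapped-Gaussian bump of
#' feature coefficients centred on the nominal orientation (width 20
#' degrees, height 2 by default). Zero-contrast rows are the zero-signal
#' patch family. Optional pixel noise turns the bank into noisy-sample
#' stimuli; generation is a pure function of (parameters, seed).
#'
#' @param model `gsm_model`.
#' @param orientations nominal orientations, degrees (wrapped into
#'   \[-90, 90) with a warning if outside).
#' @param contrast_levels nonnegative contrasts; include 0 for
#'   spontaneous-activity runs.
#' @param noiseless if `TRUE` (default) omit pixel noise.
#' @param bump_width,bump_height shape of `y_star` (degrees, amplitude).
#' @param seed RNG seed (used only when `noiseless = FALSE`).
#' @return object of class `stimulus_bank` with `patches` (stimuli x
#'   pixels), `contrast_levels`, `orientations` (per stimulus), `ids`,
#'   `y_star` (per stimulus list), `provenance`.
#' @export
make_bank <- function(model, orientations = c(-45, 0, 45),
                      contrast_levels = c(0, 0.25, 0.5, 1, 2, 4),
                      noiseless = TRUE, bump_width = 20, bump_height = 2,
                      seed = 1) {
  stopifnot(all(contrast_levels >= 0))
  if (any(orientations < -90 | orientations >= 90)) {
    warning("orientations outside [-90, 90) were wrapped")
    orientations <- wrap_orientation(orientations)
  }
  grid <- expand.grid(ori = orientations, z = contrast_levels,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  patches <- matrix(0, n, model$n_pixels)
  ys <- vector("list", n)
  ids <- character(n)
  set.seed(seed)
  for (i in seq_len(n)) {
    ori <- grid$ori[i]; z <- grid$z[i]
    y_star <- bump_height *
      ring_kernel(orientation_distance(model$orientations, ori), bump_width)
    signal <- if (z > 0) z * drop(model$A %*% y_star) else rep(0, model$n_pixels)
    if (!noiseless)
      signal <- signal + sqrt(model$sigma_x2) * stats::rnorm(model$n_pixels)
    patches[i, ] <- signal
    ys[[i]] <- y_star
    ids[i] <- sprintf("ori%+03d_z%g", round(ori), z)
  }
  stopifnot(!anyDuplicated(ids), all(is.finite(patches)))
  bank <- list(patches = patches, contrast_levels = grid$z,
               orientations = grid$ori, ids = ids, y_star = ys,
               provenance = list(kind = "deterministic-bank",
                                 orientations = orientations,
                                 contrasts = contrast_levels,
                                 noiseless = noiseless,
                                 bump_width = bump_width,
                                 bump_height = bump_height, seed = seed))
  class(bank) <- "stimulus_bank"
  bank
}

#' @export
print.stimulus_bank <- function(x, ...) {
  cat("stimulus_bank:", nrow(x$patches), "patches (",
      length(unique(x$orientations)), "orientations x",
      length(unique(x$contrast_levels)), "contrasts ),",
      ncol(x$patches), "pixels\n")
  invisible(x)
}

#' Random training sample from the full generative model
#'
#' Draws `n` patches from the forward model with contrasts from the gamma
#' prior, retaining the latent records `(y, z)` for every patch.
#'
#' @param model `gsm_model`.
#' @param n number of patches.
#' @param seed RNG seed.
#' @return `stimulus_bank` whose `y_star` holds the drawn `y` and whose
#'   `contrast_levels` holds the drawn `z`.
#' @export
make_training_sample <- function(model, n, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  Lc <- t(chol(model$C))
  sh <- model$contrast_prior["shape"]; sc <- model$contrast_prior["scale"]
  patches <- matrix(0, n, model$n_pixels)
  ys <- vector("list", n)
  zs <- numeric(n)
  for (i in seq_len(n)) {
    z <- stats::rgamma(1, shape = sh, scale = sc)
    y <- drop(Lc %*% stats::rnorm(model$n_latents))
    patches[i, ] <- z * drop(model$A %*% y) +
      sqrt(model$sigma_x2) * stats::rnorm(model$n_pixels)
    ys[[i]] <- y; zs[i] <- z
  }
  bank <- list(patches = patches, contrast_levels = zs,
               orientations = rep(NA_real_, n),
               ids = sprintf("train%05d", seq_len(n)), y_star = ys,
               provenance = list(kind = "training-sample", n = n, seed = seed))
  class(bank) <- "stimulus_bank"
  bank
}

#' Write a stimulus bank manifest to CSV
#' @param bank `stimulus_bank`.
#' @param path output CSV file.
#' @export
write_bank_manifest <- function(bank, path) {
  utils::write.csv(data.frame(id = bank$ids,
                              orientation_deg = bank$orientations,
                              contrast = bank$contrast_levels),
                   path, row.names = FALSE)
  invisible(path)
}
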