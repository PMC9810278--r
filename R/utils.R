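#' Wrapped orientation distance
#'
#' Distance between orientations with period 180 degrees:
#' `d(a, b) = min(|a - b| mod 180, 180 - |a - b| mod 180)`.
#'
#' @param a,b orientations in degrees (vectors recycle).
#' @return nonnegative distances in degrees, at most 90.
#' @export
orientation_distance <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Wrap orientations into [-90, 90)
#' @param theta orientations in degrees.
#' @return equivalent orientations in `[-90, 90)`.
#' @export
wrap_orientation <- function(theta) {
  ((theta + 90) %% 180) - 90
}

# Gaussian kernel periodized over the 180-degree orientation circle
# (sum over wrap-around images). Periodization keeps kernel matrices
# positive semidefinite for any width, unlike the bare min-distance
# Gaussian; for widths well below 90 degrees the two coincide.
ring_kernel <- function(d, width) {
  stopifnot(width > 0)
  out <- 0
  for (kk in -2:2) out <- out + exp(-(d + 180 * kk)^2 / (2 * width^2))
  out / ring_kernel_norm(width)
}

ring_kernel_norm <- function(width) {
  s <- 0
  for (kk in -2:2) s <- s + exp(-(180 * kk)^2 / (2 * width^2))
  s
}

# Kernel matrix over a set of orientations.
ring_kernel_matrix <- function(orientations, width) {
  d <- outer(orientations, orientations, orientation_distance)
  ring_kernel(d, width)
}

#' Derive a child seed from a master seed and a stage label
#'
#' Stable, platform-independent derivation so that one master seed
#' determines every stage's RNG stream independently. The label is hashed
#' with a small polynomial rolling hash; the result stays below 2^31.
#'
#' @param master integer master seed.
#' @param label character stage label.
#' @return integer child seed in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(length(label) == 1L, is.character(label))
  h <- as.double(master %% 2147483647)
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
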