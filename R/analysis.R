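#' Stationary response moments of a trajectory
#'
#' Per-cell mean and standard deviation of membrane potentials and rates,
#' computed from samples taken every `thin` ms after discarding `burn_in`
#' ms. With the reference protocol (`thin = 200`) samples 200 ms apart are
#' effectively independent.
#'
#' @param traj `trajectory` from [simulate_ring()].
#' @param burn_in transient to discard, ms.
#' @param thin sampling interval, ms (multiple of the recording interval).
#' @return list with `mean_u`, `sd_u`, `mean_r`, `sd_r` (per neuron) and
#'   `n_samples`.
#' @export
stationary_moments <- function(traj, burn_in = 500, thin = 200) {
  step <- round(thin / traj$dt)
  if (step < 1 || abs(step * traj$dt - thin) > 1e-9)
    stop("thin must be a positive multiple of the recording interval")
  keep <- which(traj$t >= burn_in)
  keep <- keep[seq(1, length(keep), by = step)]
  if (length(keep) < 2) stop("fewer than 2 samples after burn-in/thinning")
  U <- traj$u[keep, , drop = FALSE]
  R <- traj$r[keep, , drop = FALSE]
  list(mean_u = colMeans(U), sd_u = apply(U, 2, stats::sd),
       mean_r = colMeans(R), sd_r = apply(R, 2, stats::sd),
       n_samples = length(keep))
}

#' Local field potential of a trajectory
#'
#' The across-cell average membrane potential at each time step.
#'
#' @param traj `trajectory`.
#' @param cells `"all"` (default), `"E"` or `"I"`.
#' @return numeric time series (same grid as `traj$t`).
#' @export
lfp <- function(traj, cells = c("all", "E", "I")) {
  cells <- match.arg(cells)
  N <- traj$n_pairs
  idx <- switch(cells, all = seq_len(2 * N), E = seq_len(N), I = N + seq_len(N))
  rowMeans(traj$u[, idx, drop = FALSE])
}

#' Welch power spectral density
#'
#' Averaged periodogram over Hann-tapered, overlapping segments with the
#' per-segment mean removed. One-sided density normalized so that the
#' integral over frequency approximates the series variance (Parseval).
#'
#' @param series numeric time series.
#' @param fs sampling frequency, Hz.
#' @param window_s segment length, s (default 1).
#' @param overlap fractional segment overlap (default 0.5).
#' @return object of class `spectrum_result`: `freqs` (Hz), `power`,
#'   `method_params`, `gamma_band`, and gamma statistics `f_peak`,
#'   `gamma_power` (filled by [gamma_stats()]).
#' @export
power_spectrum <- function(series, fs, window_s = 1, overlap = 0.5) {
  series <- as.numeric(series)
  nw <- round(window_s * fs)
  if (length(series) < 2 * nw)
    stop("series shorter than two windows (", 2 * nw, " samples needed)")
  if (fs / 2 < 80)
    stop("sampling rate too low: Nyquist ", fs / 2,
         " Hz does not cover the 20-80 Hz gamma band")
  hop <- max(1, round(nw * (1 - overlap)))
  starts <- seq(1, length(series) - nw + 1, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nw) / (nw + 1)))  # Hann taper
  norm <- fs * sum(w^2)
  nf <- nw %/% 2 + 1
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- series[s0:(s0 + nw - 1)]
    seg <- (seg - mean(seg)) * w
    ft <- stats::fft(seg)[seq_len(nf)]
    acc <- acc + (Mod(ft)^2) / norm
  }
  pxx <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nw is even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nw %% 2 == 0) dbl[nf] <- 1
  pxx <- pxx * dbl
  freqs <- (seq_len(nf) - 1) * fs / nw
  out <- list(freqs = freqs, power = pxx,
              method_params = list(window_s = window_s, overlap = overlap,
                                   n_segments = length(starts), fs = fs,
                                   detrend = "per-segment mean"),
              gamma_band = c(20, 80), f_peak = NA_real_, gamma_power = NA_real_)
  class(out) <- "spectrum_result"
  gs <- gamma_stats(out)
  out$f_peak <- gs$f_peak
  out$gamma_power <- gs$gamma_power
  out
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat("spectrum_result:", length(x$freqs), "frequencies up to",
      max(x$freqs), "Hz\n")
  cat("  gamma band", x$gamma_band[1], "-", x$gamma_band[2], "Hz: f_peak =",
      if (is.na(x$f_peak)) "none" else paste(round(x$f_peak, 1), "Hz"),
      ", gamma_power =", signif(x$gamma_power, 4), "\n")
  invisible(x)
}

#' Gamma-band statistics of a power spectrum
#'
#' `f_peak` is the frequency of the largest local maximum strictly inside
#' the gamma band (20-80 Hz); a spectrum monotone on the band has no peak
#' (`NA`). Ties go to the lower frequency. `gamma_power` is the trapezoidal
#' integral of the density over the band.
#'
#' @param spec `spectrum_result` (or list with `freqs`, `power`).
#' @param band frequency band, Hz (default `c(20, 80)`).
#' @return list with `f_peak` (Hz or `NA`) and `gamma_power`.
#' @export
gamma_stats <- function(spec, band = c(20, 80)) {
  f <- spec$freqs; p <- spec$power
  if (max(f) < band[2] || min(f) > band[1])
    stop("spectrum does not cover the gamma band")
  # local maxima on the full grid, then restrict strictly inside the band
  n <- length(p)
  is_max <- c(FALSE, p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] >= p[3:n],
              FALSE)
  cand <- which(is_max & f > band[1] & f < band[2])
  f_peak <- if (length(cand)) {
    best <- cand[order(-p[cand], f[cand])][1]
    f[best]
  } else NA_real_

  inb <- f >= band[1] & f <= band[2]
  fi <- f[inb]; pi_ <- p[inb]
  # extend to the exact band edges by linear interpolation
  if (min(fi) > band[1]) {
    pi_ <- c(stats::approx(f, p, band[1])$y, pi_); fi <- c(band[1], fi)
  }
  if (max(fi) < band[2]) {
    pi_ <- c(pi_, stats::approx(f, p, band[2])$y); fi <- c(fi, band[2])
  }
  gp <- sum(diff(fi) * (head(pi_, -1) + tail(pi_, -1)) / 2)
  list(f_peak = f_peak, gamma_power = gp)
}

# truncated-normal sampler (lower bound 0, no upper bound), inverse CDF
rtruncnorm0 <- function(n, mean, sd) {
  if (sd <= 0) return(rep(max(mean, 0), n))
  F0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(F0 + stats::runif(n) * (1 - F0), mean, sd)
}

#' Trial-averaged transient response to stimulus onset
#'
#' Simulates `n_trials` onset trials. In each trial the network rests under
#' the baseline drive; at onset each E-I pair's feedforward input switches
#' to the stimulus-driven value after a pair-specific random delay
#' (truncated Gaussian, mean 45 ms, SD 5 ms, truncated at 0; shared within
#' the pair, redrawn per trial). The mean firing rate across E cells and
#' trials is smoothed with a 10-ms moving average and its maximum after
#' onset is reported.
#'
#' @param net `ring_network`.
#' @param patch pixel vector (stimulus), or a precomputed drive via `h`.
#' @param n_trials number of trials (default 100).
#' @param seed integer seed.
#' @param pre_ms spontaneous period before onset (default 500).
#' @param post_ms recorded period after onset (default 500).
#' @param dt integration step, ms.
#' @param window_ms smoothing window (default 10).
#' @param delay_mean,delay_sd onset-delay distribution, ms (default 45, 5).
#' @param h optional drive vector overriding `patch`.
#' @param noise logical; `FALSE` gives the deterministic response.
#' @return object of class `transient_summary` with `t` (ms relative to
#'   onset), `mean_rate`, `peak_rate`, `peak_time`, `spont_rate`,
#'   `n_trials`, `window_ms`, `delay_params`.
#' @export
transient_response <- function(net, patch = NULL, n_trials = 100, seed = 1,
                               pre_ms = 500, post_ms = 500, dt = 0.2,
                               window_ms = 10, delay_mean = 45, delay_sd = 5,
                               h = NULL, noise = TRUE) {
  if (n_trials < 1) stop("n_trials must be positive")
  if (is.null(h)) h <- feedforward_input(net, patch)
  h_pre <- baseline_input(net)
  N <- net$n_pairs
  u0 <- fixed_point(net, h_pre)
  duration <- pre_ms + post_ms
  traces <- matrix(0, nrow = round(duration) + 1, ncol = n_trials)
  for (tr in seq_len(n_trials)) {
    trial_seed <- derive_seed(seed, paste0("transient-trial-", tr))
    set.seed(trial_seed)
    delays <- rtruncnorm0(N, delay_mean, delay_sd)
    onset_ms <- rep(pre_ms + delays, 2)   # shared within each E-I pair
    traj <- simulate_ring(net, h, duration = duration, dt = dt,
                          seed = derive_seed(trial_seed, "sim"),
                          record_every = 1, u0 = u0, noise = noise,
                          h_pre = h_pre, onset_ms = onset_ms)
    traces[, tr] <- rowMeans(traj$r[, seq_len(N), drop = FALSE])
  }
  mean_rate <- rowMeans(traces)
  # centered moving average over window_ms (recording grid is 1 ms)
  kern <- rep(1 / (window_ms + 1), window_ms + 1)
  sm <- stats::filter(mean_rate, kern, sides = 2)
  sm[is.na(sm)] <- mean_rate[is.na(sm)]
  t_rel <- seq(0, duration) - pre_ms
  post <- which(t_rel >= 0)
  ipk <- post[which.max(sm[post])]
  out <- list(t = t_rel, mean_rate = as.numeric(sm),
              raw_rate = mean_rate,
              peak_rate = as.numeric(sm[ipk]), peak_time = t_rel[ipk],
              spont_rate = mean(sm[t_rel < 0]),
              n_trials = n_trials, window_ms = window_ms,
              delay_params = c(mean = delay_mean, sd = delay_sd))
  class(out) <- "transient_summary"
  out
}

#' @export
print.transient_summary <- function(x, ...) {
  cat("transient_summary:", x$n_trials, "trials; peak",
      round(x$peak_rate, 3), "Hz at", x$peak_time, "ms after onset",
      "( spontaneous", round(x$spont_rate, 3), "Hz )\n")
  invisible(x)
}

#' Mean recurrent E and I input onto each E cell
#'
#' Time-averaged excitatory recurrent input `sum_{j in E} W_ij r_j` and the
#' magnitude of the inhibitory recurrent input `|sum_{j in I} W_ij r_j|`
#' for every E cell, from a recorded trajectory.
#'
#' @param net `ring_network`.
#' @param traj `trajectory` simulated from `net`.
#' @param burn_in ms to discard before averaging.
#' @return list with `excitatory` and `inhibitory_magnitude` (length
#'   `n_pairs`).
#' @export
input_decomposition <- function(net, traj, burn_in = 0) {
  N <- net$n_pairs
  keep <- traj$t >= burn_in
  rbar <- colMeans(traj$r[keep, , drop = FALSE])
  exc <- drop(net$W[seq_len(N), seq_len(N), drop = FALSE] %*% rbar[seq_len(N)])
  inh <- drop(net$W[seq_len(N), N + seq_len(N), drop = FALSE] %*% rbar[N + seq_len(N)])
  list(excitatory = exc, inhibitory_magnitude = abs(inh))
}
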