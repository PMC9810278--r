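#' Scale inhibitory synapses (inhibitory deficit)
#'
#' Multiplies the inhibitory columns of the recurrent weight matrix by
#' `(1 - delta_I)`, leaving excitatory columns and every other field
#' bitwise untouched. Dale's principle and the zero pattern of `W` are
#' preserved exactly.
#'
#' @param net `ring_network`.
#' @param delta_I deficit fraction in `[0, 1)`.
#' @return modified `ring_network`.
#' @export
scale_inhibition <- function(net, delta_I) {
  if (delta_I < 0 || delta_I >= 1) stop("delta_I must lie in [0, 1)")
  N <- net$n_pairs
  net$W[, N + seq_len(N)] <- (1 - delta_I) * net$W[, N + seq_len(N)]
  net$deficit <- c(net$deficit, list(delta_I = delta_I))
  net
}

#' Scale excitatory synapses (homeostatic compensation)
#'
#' Mirror of [scale_inhibition()] on the excitatory columns:
#' `W_E <- (1 - delta_E) W_E`.
#'
#' @param net `ring_network`.
#' @param delta_E fraction in `[0, 1)`.
#' @return modified `ring_network`.
#' @export
scale_excitation <- function(net, delta_E) {
  if (delta_E < 0 || delta_E >= 1) stop("delta_E must lie in [0, 1)")
  N <- net$n_pairs
  net$W[, seq_len(N)] <- (1 - delta_E) * net$W[, seq_len(N)]
  net$deficit <- c(net$deficit, list(delta_E = delta_E))
  net
}

#' Default spontaneous-activity protocol
#'
#' Simulation settings under which the mean spontaneous activity is
#' measured: zero-contrast (baseline) drive, fixed seed, stationary window.
#'
#' @param duration simulated time, ms.
#' @param burn_in discarded transient, ms.
#' @param thin sampling interval, ms.
#' @param dt integration step, ms.
#' @param seed fixed RNG seed (common random numbers across comparisons).
#' @param cells which population enters the average (`"E"` by default; the
#'   switch exists because "activity" could also be read over all cells).
#' @param measure `"u"` (default) or `"rate"`. Under the sampling reading of
#'   spontaneous activity, the E-cell membrane potential represents the
#'   prior over latent intensities, so preserving its baseline mean
#'   preserves the represented prior; the rate-based variant is kept as a
#'   switch.
#' @return protocol list.
#' @export
spontaneous_protocol <- function(duration = 10000, burn_in = 500, thin = 10,
                                 dt = 0.2, seed = 1234, cells = c("E", "all"),
                                 measure = c("u", "rate")) {
  list(duration = duration, burn_in = burn_in, thin = thin, dt = dt,
       seed = seed, cells = match.arg(cells), measure = match.arg(measure))
}

#' Mean spontaneous activity under a fixed protocol
#'
#' Simulates the network under the baseline (zero-contrast) drive with the
#' protocol's seed and returns the mean E-cell firing rate (or membrane
#' potential) over the stationary window. Same protocol, same seed: same
#' value, bit for bit.
#'
#' @param net `ring_network`.
#' @param protocol from [spontaneous_protocol()].
#' @return scalar mean spontaneous activity.
#' @export
spontaneous_mean <- function(net, protocol = spontaneous_protocol()) {
  h <- baseline_input(net)
  traj <- simulate_ring(net, h, duration = protocol$duration,
                        dt = protocol$dt, seed = protocol$seed,
                        record_every = protocol$thin)
  sm <- stationary_moments(traj, burn_in = protocol$burn_in,
                           thin = protocol$thin)
  N <- net$n_pairs
  idx <- if (protocol$cells == "E") seq_len(N) else seq_len(2 * N)
  val <- if (protocol$measure == "rate") sm$mean_r[idx] else sm$mean_u[idx]
  mean(val)
}

#' Homeostatic grid search for the compensating excitatory scaling
#'
#' For a given inhibitory deficit `delta_I`, evaluates the homeostatic cost
#' `C_h(delta_E) = |mu_s(NT) - mu_s(ASD(delta_I, delta_E))|` over a grid of
#' candidate `delta_E` values (common random numbers: every evaluation
#' reuses the protocol seed) and returns the minimizer. Composition order
#' is inhibition scaling first, then excitation scaling. The coarse grid
#' (step 0.002 from 0 to `delta_I` by default) is refined once around its
#' argmin.
#'
#' @param net_NT the unperturbed network.
#' @param delta_I inhibitory deficit fraction.
#' @param grid candidate `delta_E` values (default `seq(0, delta_I, 0.002)`).
#' @param protocol spontaneous-activity protocol.
#' @param refine logical: refine once around the coarse argmin (step /5).
#' @return list with `delta_E`, `cost_table` (data.frame `delta_E`, `cost`),
#'   `mu_s_NT`, `mu_s_ASD` (at the optimum), `protocol`.
#' @export
homeostatic_adapt <- function(net_NT, delta_I,
                              grid = NULL,
                              protocol = spontaneous_protocol(),
                              refine = TRUE) {
  if (delta_I < 0 || delta_I >= 1) stop("delta_I must lie in [0, 1)")
  if (is.null(grid)) grid <- seq(0, delta_I, by = 0.002)
  if (!length(grid)) stop("empty delta_E grid")
  grid <- sort(unique(pmax(grid, 0)))
  if (delta_I == 0) {
    mu0 <- spontaneous_mean(net_NT, protocol)
    return(list(delta_E = 0,
                cost_table = data.frame(delta_E = 0, cost = 0),
                mu_s_NT = mu0, mu_s_ASD = mu0, protocol = protocol))
  }
  mu_NT <- spontaneous_mean(net_NT, protocol)
  net_I <- scale_inhibition(net_NT, delta_I)
  eval_grid <- function(g) {
    vapply(g, function(dE) {
      mu <- tryCatch(spontaneous_mean(scale_excitation(net_I, dE), protocol),
                     error = function(e) NA_real_)
      abs(mu_NT - mu)
    }, numeric(1))
  }
  cost <- eval_grid(grid)
  tab <- data.frame(delta_E = grid, cost = cost)
  if (all(is.na(cost))) stop("all delta_E candidates were unstable")
  best <- grid[which.min(cost)]
  if (refine && length(grid) > 1) {
    step <- min(diff(grid))
    fine <- setdiff(seq(max(0, best - step), best + step, by = step / 5), grid)
    if (length(fine)) {
      cost_f <- eval_grid(fine)
      tab <- rbind(tab, data.frame(delta_E = fine, cost = cost_f))
      tab <- tab[order(tab$delta_E), ]
    }
  }
  tab <- tab[!is.na(tab$cost), ]
  best <- tab$delta_E[which.min(tab$cost)]
  mu_best <- spontaneous_mean(scale_excitation(net_I, best), protocol)
  list(delta_E = best, cost_table = tab, mu_s_NT = mu_NT, mu_s_ASD = mu_best,
       protocol = protocol)
}

#' Build the perturbed (ASD) network from the unperturbed (NT) one
#'
#' Applies the inhibitory deficit and the homeostatic excitatory scaling,
#' resolving `delta_E` by grid search when `"auto"`. The provenance record
#' keeps the deltas, the full cost table, and the residual spontaneous-rate
#' mismatch at the optimum.
#'
#' @param net_NT unperturbed `ring_network`.
#' @param delta_I inhibitory deficit fraction (reference value 0.1).
#' @param delta_E explicit fraction or `"auto"` (default).
#' @param grid candidate grid for `"auto"` (see [homeostatic_adapt()]).
#' @param protocol spontaneous-activity protocol.
#' @return `ring_network` with a `provenance` field.
#' @export
make_asd_network <- function(net_NT, delta_I, delta_E = "auto", grid = NULL,
                             protocol = spontaneous_protocol()) {
  prov <- list(delta_I = delta_I, protocol = protocol)
  if (identical(delta_E, "auto")) {
    ha <- homeostatic_adapt(net_NT, delta_I, grid = grid, protocol = protocol)
    delta_E <- ha$delta_E
    prov$cost_table <- ha$cost_table
    prov$mu_s_NT <- ha$mu_s_NT
    prov$mu_s_ASD <- ha$mu_s_ASD
    prov$residual <- abs(ha$mu_s_NT - ha$mu_s_ASD)
  }
  prov$delta_E <- delta_E
  net <- scale_excitation(scale_inhibition(net_NT, delta_I), delta_E)
  net$provenance <- prov
  net
}
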