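#' Calibration targets from the ideal observer
#'
#' Maps GSM posterior moments on a stimulus bank to network targets under
#' the convention that latent i is represented by E cell i: the target for
#' the mean E-cell membrane potential is the posterior mean of the latent
#' intensities, and the target SD is the posterior standard deviation.
#'
#' @param model `gsm_model` (n_latents must equal the network's n_pairs).
#' @param bank `stimulus_bank`.
#' @param z_grid contrast grid for the marginalized posterior; a single
#'   value gives conditional-posterior targets.
#' @return object of class `calibration_target`: per-stimulus list of
#'   `id`, `mean`, `sd`, plus the `bank`.
#' @export
gsm_targets <- function(model, bank, z_grid = default_z_grid()) {
  per <- lapply(seq_len(nrow(bank$patches)), function(i) {
    ps <- posterior_moments(model, bank$patches[i, ], z_grid,
                            stimulus_id = bank$ids[i])
    list(id = bank$ids[i], mean = ps$mean, sd = ps$sd)
  })
  out <- list(per_stimulus = per, bank = bank, source = "gsm")
  class(out) <- "calibration_target"
  out
}

#' Calibration targets from a reference network
#'
#' Simulated stationary E-cell moments of a known network on the bank;
#' used for self-consistency and parameter-recovery experiments.
#'
#' @param net reference `ring_network`.
#' @param bank `stimulus_bank`.
#' @param sim_cfg simulation settings (see [calib_sim_cfg()]).
#' @return `calibration_target`.
#' @export
network_targets <- function(net, bank, sim_cfg = calib_sim_cfg()) {
  per <- lapply(seq_len(nrow(bank$patches)), function(i) {
    mom <- e_cell_moments(net, bank$patches[i, ], sim_cfg,
                          seed_tag = bank$ids[i])
    list(id = bank$ids[i], mean = mom$mean, sd = mom$sd)
  })
  out <- list(per_stimulus = per, bank = bank, source = "network")
  class(out) <- "calibration_target"
  out
}

#' Simulation settings used inside the calibration loss
#'
#' Shorter than the final analysis protocol so a loss evaluation stays
#' cheap; the seed is fixed so evaluations use common random numbers and
#' the loss is quasi-deterministic.
#'
#' @param duration simulated ms per stimulus.
#' @param burn_in discarded ms.
#' @param thin sampling interval, ms.
#' @param dt integration step, ms.
#' @param seed base seed (per-stimulus seeds are derived from it).
#' @return list.
#' @export
calib_sim_cfg <- function(duration = 30000, burn_in = 100, thin = 20,
                          dt = 0.2, seed = 99) {
  list(duration = duration, burn_in = burn_in, thin = thin, dt = dt,
       seed = seed)
}

# stationary mean/SD of E-cell membrane potentials for one stimulus
e_cell_moments <- function(net, patch, sim_cfg, seed_tag = "x") {
  h <- feedforward_input(net, patch)
  traj <- simulate_ring(net, h, duration = sim_cfg$duration, dt = sim_cfg$dt,
                        seed = derive_seed(sim_cfg$seed, seed_tag),
                        record_every = sim_cfg$thin)
  sm <- stationary_moments(traj, burn_in = sim_cfg$burn_in,
                           thin = sim_cfg$thin)
  N <- net$n_pairs
  list(mean = sm$mean_u[seq_len(N)], sd = sm$sd_u[seq_len(N)])
}

#' Decode a named log-parameter vector into a full parameter list
#'
#' Parameter names: `JEE`, `JEI`, `JIE`, `JII` (kernel amplitudes), `wEE`,
#' `wEI`, `wIE`, `wII` (kernel widths), `noise_sd`, `noise_width`,
#' `gain_E`, `gain_I`, `baseline_E`, `baseline_I`, `tau_ratio`.
#'
#' @param theta named numeric vector of log-values.
#' @param base_params full parameter list ([ring_defaults()]) to patch.
#' @return parameter list for [build_ring()].
#' @export
decode_params <- function(theta, base_params) {
  p <- base_params
  for (nm in names(theta)) {
    val <- exp(theta[[nm]])
    switch(nm,
      JEE = { p$J[["EE"]] <- val }, JEI = { p$J[["EI"]] <- val },
      JIE = { p$J[["IE"]] <- val }, JII = { p$J[["II"]] <- val },
      wEE = { p$width[["EE"]] <- val }, wEI = { p$width[["EI"]] <- val },
      wIE = { p$width[["IE"]] <- val }, wII = { p$width[["II"]] <- val },
      noise_sd = { p$noise$sd_E <- val; p$noise$sd_I <- val },
      noise_width = { p$noise$width <- val },
      gain_E = { p$ff$gain_E <- val }, gain_I = { p$ff$gain_I <- val },
      baseline_E = { p$ff$baseline_E <- val },
      baseline_I = { p$ff$baseline_I <- val },
      tau_ratio = { p$tau_I <- p$tau_E / val },
      stop("unknown calibration parameter: ", nm))
  }
  p
}

#' Encode named parameters of a parameter list as a log vector
#'
#' Inverse of [decode_params()] on the selected names.
#'
#' @param params full parameter list.
#' @param names character vector of parameter names to extract.
#' @return named numeric vector of log-values.
#' @export
encode_params <- function(params, names) {
  vapply(names, function(nm) {
    val <- switch(nm,
      JEE = params$J[["EE"]], JEI = params$J[["EI"]],
      JIE = params$J[["IE"]], JII = params$J[["II"]],
      wEE = params$width[["EE"]], wEI = params$width[["EI"]],
      wIE = params$width[["IE"]], wII = params$width[["II"]],
      noise_sd = params$noise$sd_E, noise_width = params$noise$width,
      gain_E = params$ff$gain_E, gain_I = params$ff$gain_I,
      baseline_E = params$ff$baseline_E, baseline_I = params$ff$baseline_I,
      tau_ratio = params$tau_E / params$tau_I,
      stop("unknown calibration parameter: ", nm))
    log(val)
  }, numeric(1))
}

#' Moment-matching loss for ring-kernel parameters
#'
#' `loss = sum_stimuli ||mu_net - mu_target||^2 +
#'  lambda * ||sd_net - sd_target||^2`, with the network moments estimated
#' from seeded simulations of E-cell membrane potentials (common random
#' numbers across calls). An unstable candidate returns a large finite
#' penalty instead of throwing.
#'
#' @param theta named log-parameter vector (see [decode_params()] names).
#' @param targets `calibration_target`.
#' @param base_params full parameter list the vector patches into.
#' @param ff_filters feedforward filter matrix for [build_ring()].
#' @param sim_cfg from [calib_sim_cfg()].
#' @param lambda weight of the SD term (default 1).
#' @param n_pairs ring size.
#' @return scalar loss (>= 0); attribute `"unstable"` flags penalty returns.
#' @export
moment_loss <- function(theta, targets, base_params, ff_filters,
                        sim_cfg = calib_sim_cfg(), lambda = 1,
                        n_pairs = length(targets$per_stimulus[[1]]$mean)) {
  params <- decode_params(theta, base_params)
  net <- tryCatch(build_ring(n_pairs, params, ff_filters = ff_filters),
                  error = function(e) NULL)
  if (is.null(net)) return(structure(1e12, unstable = TRUE))
  total <- 0
  for (tg in targets$per_stimulus) {
    i <- match(tg$id, targets$bank$ids)
    mom <- tryCatch(
      e_cell_moments(net, targets$bank$patches[i, ], sim_cfg, seed_tag = tg$id),
      error = function(e) NULL)
    if (is.null(mom)) return(structure(1e12, unstable = TRUE))
    total <- total + sum((mom$mean - tg$mean)^2) +
      lambda * sum((mom$sd - tg$sd)^2)
  }
  total
}

#' Calibrate ring-kernel parameters to moment targets
#'
#' Derivative-free minimization of [moment_loss()] on the log-parameter
#' vector. The default engine is Nelder-Mead simplex search (which follows
#' the curved, correlated valleys of the kernel-parameter landscape); a
#' coordinate pattern search with step halving, pattern moves, and random
#' diagonal probes is available as `engine = "pattern"`. Both are monotone
#' in the accepted iterate: the returned loss never exceeds the initial
#' one, and every evaluation uses common random numbers, so the loss is a
#' deterministic function of the parameters.
#'
#' @param init_theta named log-parameter starting vector (e.g. from
#'   [encode_params()]).
#' @param targets `calibration_target`.
#' @param base_params full parameter list (fixed entries).
#' @param ff_filters feedforward filters.
#' @param budget maximum number of loss evaluations (0 returns the init).
#' @param engine `"nelder-mead"` (default) or `"pattern"`.
#' @param step0 initial log-step for the pattern engine (default 0.15).
#' @param min_step pattern engine stops below this step (default 0.01).
#' @param lambda SD-term weight.
#' @param sim_cfg simulation settings for the loss.
#' @param n_pairs ring size.
#' @return list with `net` (best network), `theta`, `loss`, `trace`
#'   (data.frame of evaluations), `report` (seeds, budget spent).
#' @export
calibrate <- function(init_theta, targets, base_params, ff_filters,
                      budget = 200, engine = c("nelder-mead", "pattern"),
                      step0 = 0.15, min_step = 0.01,
                      lambda = 1, sim_cfg = calib_sim_cfg(),
                      n_pairs = length(targets$per_stimulus[[1]]$mean)) {
  engine <- match.arg(engine)
  evals <- 0
  trace <- data.frame(eval = integer(), loss = numeric(),
                      param = character(), stringsAsFactors = FALSE)
  loss_fn <- function(th, tag = "eval") {
    v <- moment_loss(th, targets, base_params, ff_filters, sim_cfg, lambda,
                     n_pairs)
    evals <<- evals + 1
    trace <<- rbind(trace, data.frame(eval = evals, loss = as.numeric(v),
                                      param = tag))
    as.numeric(v)
  }
  theta <- init_theta
  if (budget <= 0) {
    net <- build_ring(n_pairs, decode_params(theta, base_params), ff_filters)
    return(list(net = net, theta = theta, loss = NA_real_, trace = trace,
                report = list(budget = 0, evals = 0, seed = sim_cfg$seed,
                              engine = engine)))
  }
  f0 <- loss_fn(theta, "init")

  if (engine == "nelder-mead") {
    o <- stats::optim(theta, loss_fn, method = "Nelder-Mead",
                      control = list(maxit = budget, reltol = 1e-9))
    if (o$value < f0) { theta <- o$par; f0 <- o$value }
  } else {
    set.seed(derive_seed(sim_cfg$seed, "calibrate-probes"))
    step <- step0
    # Hooke-Jeeves: coordinate exploration, pattern moves along the
    # aggregate direction of a successful sweep, and random diagonal
    # probes before each step halving
    while (step >= min_step && evals < budget) {
      sweep_start <- theta
      improved <- FALSE
      for (j in seq_along(theta)) {
        for (dir in c(+1, -1)) {
          if (evals >= budget) break
          cand <- theta
          cand[j] <- cand[j] + dir * step
          fc <- loss_fn(cand, names(theta)[j])
          if (fc < f0) {
            theta <- cand; f0 <- fc; improved <- TRUE
            break
          }
        }
      }
      if (improved) {
        delta <- theta - sweep_start
        while (evals < budget && sqrt(sum(delta^2)) > 0) {
          cand <- theta + delta
          fc <- loss_fn(cand, "pattern")
          if (fc < f0) { theta <- cand; f0 <- fc } else break
        }
      } else {
        escaped <- FALSE
        for (probe in seq_len(4)) {
          if (evals >= budget) break
          dirv <- stats::rnorm(length(theta))
          dirv <- dirv / sqrt(sum(dirv^2))
          cand <- theta + step * dirv
          fc <- loss_fn(cand, "probe")
          if (fc < f0) { theta <- cand; f0 <- fc; escaped <- TRUE; break }
        }
        if (!escaped) step <- step / 2
      }
    }
  }
  net <- build_ring(n_pairs, decode_params(theta, base_params), ff_filters)
  list(net = net, theta = theta, loss = f0, trace = trace,
       report = list(budget = budget, evals = evals, seed = sim_cfg$seed,
                     engine = engine))
}
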