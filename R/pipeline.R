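#' Experiment configuration
#'
#' One serializable list controls both experimental paths: the observer
#' (GSM) settings, the stimulus bank, the network and calibration settings,
#' the inhibitory-deficit specification, the analysis protocol sizes, and a
#' master seed from which every stage derives its own seed via
#' [derive_seed()].
#'
#' @param master_seed integer master seed.
#' @param ... overrides of any top-level element.
#' @return nested configuration list.
#' @export
experiment_config <- function(master_seed = 1, ...) {
  cfg <- list(
    master_seed = master_seed,
    gsm = list(n_latents = 32, patch_side = 16, sigma_x2 = 0.25,
               kernel_params = list(variance = 1, width = 25),
               contrast_prior = c(shape = 2, scale = 1)),
    bank = list(orientations = 0, contrast_levels = c(0, 0.25, 0.5, 1, 2, 4),
                bump_width = 20, bump_height = 2),
    alpha_hypo = 1.5,
    toy = list(C = 4, A = 10, sigma_x2 = 100, x_obs = 10,
               z_values = c(0, 0.25, 0.5, 1, 2, 4)),
    ring = list(n_pairs = 32, params = ring_defaults()),
    deficit = list(delta_I = 0.1, delta_E = "auto",
                   protocol = spontaneous_protocol()),
    analysis = list(stationary_ms = 20000, stationary_burn_ms = 500,
                    stationary_thin_ms = 20,
                    spectrum_ms = 30000, spectrum_burn_ms = 500,
                    transient_trials = 20, transient_contrasts = c(2, 4),
                    dt = 0.2)
  )
  utils::modifyList(cfg, list(...))
}

#' Hypoprior path: observer-level perturbation
#'
#' Computes posterior mean and SD (averaged across latents) as a function
#' of contrast under the true prior (`alpha = 1`) and the hypoprior
#' (`alpha = alpha_hypo`), for the deterministic stimulus bank, in both the
#' contrast-marginalized and the known-contrast (conditional) variants,
#' plus the closed-form 1D toy curves.
#'
#' @param cfg from [experiment_config()].
#' @param latents `"all"` or `"aligned"`: average posterior moments over
#'   all latents or only those within the stimulus bump (|orientation
#'   difference| <= bank bump width).
#' @return list with `bank_table` (data.frame), `toy_table`, `model`,
#'   `model_hypo`, `bank`.
#' @export
run_hypoprior_path <- function(cfg = experiment_config(),
                               latents = c("all", "aligned")) {
  latents <- match.arg(latents)
  g <- cfg$gsm
  model <- gsm_model(n_latents = g$n_latents, patch_side = g$patch_side,
                     sigma_x2 = g$sigma_x2, kernel_params = g$kernel_params,
                     contrast_prior = g$contrast_prior)
  model_hypo <- apply_hypoprior(model, cfg$alpha_hypo)
  bank <- make_bank(model, orientations = cfg$bank$orientations,
                    contrast_levels = cfg$bank$contrast_levels,
                    bump_width = cfg$bank$bump_width,
                    bump_height = cfg$bank$bump_height,
                    seed = derive_seed(cfg$master_seed, "bank"))
  sel <- function(ori) {
    if (latents == "all") seq_len(model$n_latents)
    else which(orientation_distance(model$orientations, ori) <=
                 cfg$bank$bump_width)
  }
  rows <- list()
  for (i in seq_len(nrow(bank$patches))) {
    x <- bank$patches[i, ]; z <- bank$contrast_levels[i]
    idx <- sel(bank$orientations[i])
    for (variant in c("marginal", "conditional")) {
      pt <- if (variant == "marginal") posterior_moments(model, x)
            else posterior_given_z(model, x, z)
      ph <- if (variant == "marginal") posterior_moments(model_hypo, x)
            else posterior_given_z(model_hypo, x, z)
      rows[[length(rows) + 1]] <- data.frame(
        id = bank$ids[i], contrast = z, variant = variant,
        mean_true = mean(pt$mean[idx]), sd_true = mean(pt$sd[idx]),
        mean_hypo = mean(ph$mean[idx]), sd_hypo = mean(ph$sd[idx]))
    }
  }
  toy <- toy1d_curves(C = cfg$toy$C, A = cfg$toy$A,
                      sigma_x2 = cfg$toy$sigma_x2, alpha = cfg$alpha_hypo,
                      x_obs = cfg$toy$x_obs, z_values = cfg$toy$z_values)
  list(bank_table = do.call(rbind, rows), toy_table = toy,
       model = model, model_hypo = model_hypo, bank = bank)
}

# network response battery for one network across the bank
network_battery <- function(net, bank, cfg, seed_label) {
  an <- cfg$analysis
  N <- net$n_pairs
  rows <- list()
  for (i in seq_len(nrow(bank$patches))) {
    z <- bank$contrast_levels[i]
    h <- feedforward_input(net, bank$patches[i, ])
    seed_i <- derive_seed(cfg$master_seed, paste0(seed_label, "-", bank$ids[i]))
    traj <- simulate_ring(net, h, duration = an$spectrum_ms, dt = an$dt,
                          seed = seed_i, record_every = 1,
                          stimulus_id = bank$ids[i])
    sm <- stationary_moments(traj, burn_in = an$stationary_burn_ms,
                             thin = an$stationary_thin_ms)
    x <- lfp(traj); x <- x[traj$t > an$spectrum_burn_ms]
    sp <- power_spectrum(x, fs = 1000 / traj$dt)
    peak <- NA_real_
    if (z %in% an$transient_contrasts) {
      tr <- transient_response(net, bank$patches[i, ],
                               n_trials = an$transient_trials,
                               seed = derive_seed(seed_i, "transient"),
                               dt = an$dt)
      peak <- tr$peak_rate
    }
    dec <- input_decomposition(net, traj, burn_in = an$stationary_burn_ms)
    rows[[length(rows) + 1]] <- data.frame(
      id = bank$ids[i], contrast = z,
      mean_uE = mean(sm$mean_u[seq_len(N)]),
      sd_uE = mean(sm$sd_u[seq_len(N)]),
      mean_rE = mean(sm$mean_r[seq_len(N)]),
      f_peak = sp$f_peak, gamma_power = sp$gamma_power,
      peak_rate = peak,
      exc_input = mean(dec$excitatory),
      inh_input = mean(dec$inhibitory_magnitude))
  }
  do.call(rbind, rows)
}

#' Circuit path: network-level perturbation
#'
#' Builds (or accepts) the unperturbed NT-network, derives the ASD-network
#' by the inhibitory deficit plus homeostatic excitatory scaling, runs the
#' stationary, spectral, transient, and input-decomposition analyses on
#' both across the contrast bank, and tabulates the NT-vs-ASD comparison.
#'
#' @param cfg from [experiment_config()].
#' @param net_NT optional precomputed NT-network (built from
#'   `cfg$ring` otherwise).
#' @param model optional `gsm_model` (for feedforward filters and bank).
#' @return list with `nt_table`, `asd_table`, `delta` (resolution record),
#'   `net_NT`, `net_ASD`, `bank`.
#' @export
run_circuit_path <- function(cfg = experiment_config(), net_NT = NULL,
                             model = NULL) {
  if (is.null(model)) {
    g <- cfg$gsm
    model <- gsm_model(n_latents = g$n_latents, patch_side = g$patch_side,
                       sigma_x2 = g$sigma_x2, kernel_params = g$kernel_params,
                       contrast_prior = g$contrast_prior)
  }
  if (is.null(net_NT))
    net_NT <- build_ring(cfg$ring$n_pairs, cfg$ring$params,
                         ff_filters = model$A)
  bank <- make_bank(model, orientations = cfg$bank$orientations,
                    contrast_levels = cfg$bank$contrast_levels,
                    bump_width = cfg$bank$bump_width,
                    bump_height = cfg$bank$bump_height,
                    seed = derive_seed(cfg$master_seed, "bank"))
  net_ASD <- make_asd_network(net_NT, delta_I = cfg$deficit$delta_I,
                              delta_E = cfg$deficit$delta_E,
                              protocol = cfg$deficit$protocol)
  nt_table <- network_battery(net_NT, bank, cfg, "nt")
  asd_table <- network_battery(net_ASD, bank, cfg, "asd")
  list(nt_table = nt_table, asd_table = asd_table,
       delta = net_ASD$provenance, net_NT = net_NT, net_ASD = net_ASD,
       bank = bank)
}

#' Run both perturbation paths and assemble the comparison report
#'
#' The report carries the contrast-resolved tables for the observer path
#' (true prior vs hypoprior) and the circuit path (NT vs ASD network), the
#' homeostatic resolution record, and a consistency table marking, per
#' contrast, whether the two paths agree on the signs of the perturbation
#' effect on response mean and SD.
#'
#' @param cfg from [experiment_config()].
#' @param net_NT optional precomputed NT-network.
#' @return object of class `comparison_report`.
#' @export
run_all <- function(cfg = experiment_config(), net_NT = NULL) {
  hp <- run_hypoprior_path(cfg)
  cp <- run_circuit_path(cfg, net_NT = net_NT, model = hp$model)
  hp_m <- hp$bank_table[hp$bank_table$variant == "marginal", ]
  agg_hp <- stats::aggregate(hp_m[c("mean_true", "sd_true", "mean_hypo",
                                    "sd_hypo")],
                             by = list(contrast = hp_m$contrast), FUN = mean)
  nt <- cp$nt_table; asd <- cp$asd_table
  consistency <- data.frame(
    contrast = agg_hp$contrast,
    d_mean_observer = agg_hp$mean_hypo - agg_hp$mean_true,
    d_sd_observer = agg_hp$sd_hypo - agg_hp$sd_true,
    d_mean_circuit = asd$mean_uE - nt$mean_uE,
    d_sd_circuit = asd$sd_uE - nt$sd_uE)
  consistency$mean_signs_agree <-
    sign(consistency$d_mean_observer) == sign(consistency$d_mean_circuit) |
    consistency$contrast == 0
  consistency$sd_signs_agree <-
    sign(consistency$d_sd_observer) == sign(consistency$d_sd_circuit)
  rep <- list(cfg = cfg, hypoprior = hp$bank_table, toy = hp$toy_table,
              nt_table = nt, asd_table = asd, delta = cp$delta,
              consistency = consistency)
  class(rep) <- "comparison_report"
  rep
}

#' Write a comparison report to JSON
#' @param report `comparison_report`.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows", force = TRUE)
  invisible(path)
}
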