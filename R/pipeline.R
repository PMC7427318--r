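# End-to-end orchestration: configuration defaults, the full
# simulate -> preprocess -> responses -> tuning -> statistics -> QC
# pipeline on a synthetic session, and population summaries.

#' Default pipeline configuration
#'
#' All analysis thresholds default to the standard values of the method:
#' duplicate-correlation thresholds rho = 0.4 (somata) / 0.5 (boutons),
#' 25-s transient limit, 180-s / 8th-percentile baselines, 15-s response
#' kernel, 133-ms spike bins, 500 circular shifts for correlation tests,
#' 200 responsiveness shifts, 1000 selectivity and 200 modulation
#' permutations, stimulus EV > 0.01 and ON/OFF index categories at +/-0.5.
#' Generator fields control the synthetic session (number of units, tuning
#' parameter ranges, arousal gain ratio, noise level).
#'
#' @param ... named overrides of any default field.
#'
#' @return A list of class `session_config`.
#' @export
session_config <- function(...) {
  cfg <- list(
    # generator
    n_units = 6, duration = 660, dt = 0.133, coupling = 0.6,
    n_directions = 12, n_repeats = 8, trial_dur = 2, iti_range = c(3, 6),
    gain_ratio = 0.7, p_small = 2, sigma_range = c(25, 60),
    ds_range = c(0.3, 1), noise_sd = 0.1, alpha_range = c(0.3, 1),
    run_coupling = 0, n_axons = 0, seed = 1L,
    # preprocessing
    baseline_window = 180, baseline_pct = 8, rho_threshold = 0.5,
    max_transient = 25,
    # responses
    kernel_dur = 15, n_shifts_responsiveness = 200,
    # statistics
    n_shifts = 500, n_perm_selectivity = 1000, n_perm_modulation = 200,
    # receptive fields
    run_rf = FALSE, rf_lags = c(1, 2, 3), rf_ev_threshold = 0.01,
    # output
    out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop_invalid("unknown config fields: ",
                                    paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "session_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file with any subset of [session_config()] fields.
#'
#' @return A `session_config`.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(session_config, vals)
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(cfg[order(names(cfg))], f)
  unname(tools::md5sum(f))
}

# Draw a ground-truth population from the config.
draw_units <- function(cfg) {
  set.seed(cfg$seed + 1000L)
  lapply(seq_len(cfg$n_units), function(i) {
    ground_truth_unit(
      theta_p = runif(1, 0, 360),
      sigma = runif(1, cfg$sigma_range[1], cfg$sigma_range[2]),
      ds = runif(1, cfg$ds_range[1], cfg$ds_range[2]),
      p_small = cfg$p_small, p_large = cfg$p_small * cfg$gain_ratio,
      offset_small = 0, offset_large = 0,
      run_coupling = cfg$run_coupling,
      alpha_true = runif(1, cfg$alpha_range[1], cfg$alpha_range[2]))
  })
}

#' Run the complete analysis pipeline on a synthetic session
#'
#' Generates a ground-truthed session from the configuration, then runs
#' preprocessing (neuropil correction, red regression, exclusion rules),
#' kernel/scaling response estimation with the responsiveness test,
#' pupil-state trial labels, constrained tuning fits with selectivity and
#' modulation statistics, behavioral-state correlations, optional
#' receptive-field mapping, and spike QC if axons were simulated. When
#' `config$out_dir` is set, all result tables are written there as CSV.
#'
#' @param config a [session_config()].
#'
#' @return An object of class `results_bundle`: list of data.frames
#'   (`trials`, `tuning`, `correlations`, `recovery`, optionally `rf`,
#'   `spike_qc`) plus `meta` (seed, config hash).
#' @export
run_pipeline <- function(config = session_config()) {
  cfg <- config
  units <- draw_units(cfg)
  behavior <- simulate_behavior(cfg$duration, cfg$dt, cfg$coupling,
                                seed = cfg$seed)
  schedule <- simulate_grating_schedule(cfg$n_directions, cfg$n_repeats,
                                        cfg$trial_dur, cfg$iti_range,
                                        seed = cfg$seed + 1L)
  if (max(schedule$trial_onsets) + 20 > cfg$duration)
    stop_invalid("duration too short for the requested schedule")
  noise <- NULL
  if (isTRUE(cfg$run_rf))
    noise <- simulate_noise_movie(duration = cfg$duration,
                                  seed = cfg$seed + 2L)
  session <- synthesize_session(units, behavior, schedule, noise = noise,
                                noise_sd = cfg$noise_sd, seed = cfg$seed + 3L,
                                n_axons = cfg$n_axons)

  labels <- classify_trials_by_pupil(behavior, schedule)
  dirs <- schedule$directions
  n_units <- length(units)

  trials <- NULL
  tuning_rows <- vector("list", n_units)
  corr_rows <- vector("list", n_units)
  recov_rows <- vector("list", n_units)

  run_al <- smooth_and_align(behavior$running_speed, behavior$times,
                             behavior$times, sigma = 1)
  pup <- clean_pupil(behavior$pupil_area, behavior$blink_mask)
  pup_al <- smooth_and_align(pup, behavior$times, behavior$times, sigma = 1)

  for (u in seq_len(n_units)) {
    ct <- preprocess_unit(session$raw_F[, u], session$raw_N[, u],
                          session$raw_red[, u], cfg$dt)
    resp <- test_responsiveness(ct$dff, schedule, behavior$times,
                                n_shifts = cfg$n_shifts_responsiveness,
                                seed = cfg$seed + 10L + u)
    amp <- resp$model$scalings
    trials <- rbind(trials, data.frame(
      unit = u, trial = seq_along(amp), direction = dirs,
      pupil_state = labels$pupil_state, laser_state = labels$laser_state,
      amplitude = amp))

    ok <- !is.na(labels$pupil_state)
    pair <- fit_tuning_by_state(amp[ok], dirs[ok], labels$pupil_state[ok])
    tuned <- classify_tuned(amp[ok], dirs[ok])
    m <- tapply(amp[ok], dirs[ok], mean)
    sel <- vector_selectivity(as.numeric(m), as.numeric(names(m)))
    sel_p <- selectivity_significance(amp[ok], dirs[ok],
                                      n_perm = cfg$n_perm_selectivity,
                                      seed = cfg$seed + 20L + u)
    mod_p <- modulation_significance(amp[ok], dirs[ok],
                                     labels$pupil_state[ok],
                                     n_perm = cfg$n_perm_modulation,
                                     seed = cfg$seed + 30L + u)
    tuning_rows[[u]] <- data.frame(
      unit = u, alpha = ct$alpha, excluded = ct$excluded,
      responsive = resp$responsive, responsive_p = resp$p,
      is_tuned = tuned$is_tuned,
      theta_p = pair$shared$theta_p, sigma = pair$shared$sigma,
      DS = pair$shared$DS,
      P_small = pair$states$small$P, P_large = pair$states$large$P,
      offset_small = pair$states$small$offset,
      offset_large = pair$states$large$offset,
      dsi = sel$dsi, osi = sel$osi, p_dsi = sel_p$p,
      response_modulation = pair$response_modulation,
      depth_modulation = pair$depth_modulation,
      p_modulation = mod_p$p)

    st_run <- shift_test(ct$dff, run_al, n_shifts = cfg$n_shifts,
                         dt = cfg$dt, seed = cfg$seed + 40L + u)
    st_pup <- shift_test(ct$dff, pup_al, n_shifts = cfg$n_shifts,
                         dt = cfg$dt, seed = cfg$seed + 50L + u)
    corr_rows[[u]] <- data.frame(
      unit = u, variable = c("running", "pupil"),
      r = c(st_run$r, st_pup$r), p = c(st_run$p, st_pup$p),
      significant = c(st_run$significant, st_pup$significant))

    gt <- units[[u]]
    recov_rows[[u]] <- data.frame(
      unit = u,
      theta_err = abs(wrap_angle(pair$shared$theta_p - gt$theta_p)),
      ds_err = abs(pair$shared$DS - gt$ds),
      alpha_err = abs(ct$alpha - gt$alpha_true),
      gain_ratio_true = gt$p_large / gt$p_small,
      gain_ratio_est = (pair$states$large$offset + pair$states$large$P) /
        (pair$states$small$offset + pair$states$small$P))
  }

  bundle <- list(trials = trials,
                 tuning = do.call(rbind, tuning_rows),
                 correlations = do.call(rbind, corr_rows),
                 recovery = do.call(rbind, recov_rows),
                 meta = list(seed = cfg$seed, config_hash = config_hash(cfg),
                             n_units = n_units))

  if (length(session$spikes)) {
    qc <- lapply(seq_along(session$spikes), function(a) {
      s <- session$spikes[[a]]
      r <- spike_qc_chain(s$spike_times, s$amplitudes,
                          seed = cfg$seed + 60L + a)
      data.frame(axon = a, n_spikes = length(s$spike_times),
                 kept_fraction = r$kept_fraction, amp_rate_p = r$amp_rate_p,
                 excluded = r$excluded)
    })
    bundle$spike_qc <- do.call(rbind, qc)
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in setdiff(names(bundle), "meta"))
      write.csv(bundle[[nm]], file.path(cfg$out_dir, paste0(nm, ".csv")),
                row.names = FALSE)
    yaml::write_yaml(bundle$meta, file.path(cfg$out_dir, "meta.yaml"))
  }
  class(bundle) <- "results_bundle"
  bundle
}

#' Population summary of a results bundle
#'
#' Fractions of units with significant positive/negative behavioral
#' correlations, mean modulation indices among all and among
#' significantly modulated units, and mean selectivity.
#'
#' @param bundle a `results_bundle` from [run_pipeline()].
#'
#' @return A one-row data.frame of population statistics.
#' @export
summarize_population <- function(bundle) {
  if (is.null(bundle$tuning) || nrow(bundle$tuning) == 0)
    stop_invalid("empty results bundle")
  co <- bundle$correlations
  run <- co[co$variable == "running", ]
  tu <- bundle$tuning
  sig_mod <- tu$p_modulation < 0.05
  data.frame(
    frac_sig_pos_run = mean(run$significant & run$r > 0),
    frac_sig_neg_run = mean(run$significant & run$r < 0),
    mean_response_modulation = mean(tu$response_modulation, na.rm = TRUE),
    median_response_modulation = median(tu$response_modulation, na.rm = TRUE),
    mean_modulation_significant =
      if (any(sig_mod, na.rm = TRUE))
        mean(tu$response_modulation[which(sig_mod)], na.rm = TRUE)
      else NA_real_,
    frac_tuned = mean(tu$is_tuned),
    mean_dsi = mean(tu$dsi), mean_osi = mean(tu$osi))
}
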