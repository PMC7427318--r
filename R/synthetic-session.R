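#' Simulate running-speed and pupil traces
#'
#' Generates behavioral-state traces with the statistical structure the
#' downstream analyses assume: running speed is a rectified mean-reverting
#' (Ornstein-Uhlenbeck) process with a 10-s correlation time, and pupil area
#' is a lagged (1 s), smoothed mixture of the running drive (weight
#' `coupling`) and independent slow noise. Blinks are simulated as brief
#' 0.2-s dropouts marking fewer than 2\% of samples.
#'
#' @param duration total duration in seconds (at least 60).
#' @param dt sample interval in seconds.
#' @param coupling running-to-pupil coupling weight in \[0, 1\].
#' @param seed integer seed; the same seed reproduces the traces exactly.
#' @param blink_rate expected blink events per second.
#'
#' @return An object of class `behavior_traces`: a list with `times`,
#'   `running_speed` (cm/s, non-negative), `pupil_area` (arbitrary units,
#'   positive where not blinking) and `blink_mask` (logical).
#' @export
simulate_behavior <- function(duration, dt = 0.133, coupling = 0.5, seed = 1L,
                              blink_rate = 0.02) {
  if (!is.numeric(duration) || duration <= 0 || !is.numeric(dt) || dt <= 0)
    stop_invalid("duration and dt must be positive")
  if (duration < 60) stop_invalid("duration must be at least 60 s")
  if (coupling < 0 || coupling > 1) stop_invalid("coupling must be in [0, 1]")
  set.seed(as.integer(seed))

  n <- floor(duration / dt)
  times <- (seq_len(n) - 1L) * dt

  # Rectified OU: correlation time 10 s, mean slightly above zero so the
  # animal alternates between stationary bouts and running bouts.
  tau_run <- 10
  mu <- 2; sigma_ou <- 6
  a <- exp(-dt / tau_run)
  innov_sd <- sigma_ou * sqrt(1 - a^2)
  x <- numeric(n)
  x[1] <- mu + rnorm(1, 0, sigma_ou)
  eps <- rnorm(n - 1, 0, innov_sd)
  for (i in 2:n) x[i] <- mu + a * (x[i - 1] - mu) + eps[i - 1]
  running <- pmax(x, 0)

  # Pupil: running drive lagged by 1 s and smoothed, mixed with an
  # independent slow OU; mapped to a positive area around 1.
  lag_n <- max(1L, round(1 / dt))
  run_lag <- c(rep(running[1], lag_n), running[seq_len(n - lag_n)])
  run_sm <- gaussian_smooth(run_lag, sigma_samples = 2 / dt)
  zr <- if (sd(run_sm) > 0) (run_sm - mean(run_sm)) / sd(run_sm) else run_sm * 0

  tau_slow <- 20
  b <- exp(-dt / tau_slow)
  z <- numeric(n)
  z[1] <- rnorm(1)
  eta <- rnorm(n - 1, 0, sqrt(1 - b^2))
  for (i in 2:n) z[i] <- b * z[i - 1] + eta[i - 1]
  zs <- if (sd(z) > 0) (z - mean(z)) / sd(z) else z

  mix <- coupling * zr + sqrt(max(0, 1 - coupling^2)) * zs
  pupil <- pmax(1 + 0.3 * mix, 0.05)

  # Blinks: Poisson events of 0.2 s each.
  blink_mask <- rep(FALSE, n)
  n_blinks <- rbinom(1, n, min(1, blink_rate * dt))
  if (n_blinks > 0) {
    starts <- sample.int(n, n_blinks)
    len <- max(1L, round(0.2 / dt))
    for (s in starts) blink_mask[s:min(n, s + len - 1L)] <- TRUE
  }

  structure(list(times = times, running_speed = running, pupil_area = pupil,
                 blink_mask = blink_mask, dt = dt, seed = as.integer(seed)),
            class = "behavior_traces")
}

#' Simulate a drifting-grating trial schedule
#'
#' Directions are equally spaced on \[0, 360) and each direction appears the
#' same number of times (per laser condition when `with_laser = TRUE`);
#' trial order is randomized by `seed` and inter-trial gray-screen gaps are
#' drawn uniformly from `iti_range`. Default timing follows the standard
#' protocol of 2-s gratings separated by 3-6 s of gray screen.
#'
#' @param n_directions number of equally spaced directions (>= 4).
#' @param n_repeats repeats per direction per laser condition (>= 2).
#' @param trial_dur grating duration in seconds.
#' @param iti_range length-2 numeric, uniform range of inter-trial gaps (s).
#' @param with_laser if TRUE, every direction is additionally presented with
#'   laser on, balanced across conditions (optogenetic-inactivation layout).
#' @param seed integer seed.
#' @param t_start time of the first trial onset in seconds.
#'
#' @return An object of class `grating_schedule`: list with `trial_onsets`,
#'   `trial_duration`, `directions` (degrees) and `laser_on` (logical).
#' @export
simulate_grating_schedule <- function(n_directions = 12, n_repeats = 15,
                                      trial_dur = 2, iti_range = c(3, 6),
                                      with_laser = FALSE, seed = 1L,
                                      t_start = 10) {
  if (n_directions < 4) stop_invalid("n_directions must be >= 4")
  if (n_repeats < 2) stop_invalid("n_repeats must be >= 2")
  if (length(iti_range) != 2 || iti_range[1] < 0)
    stop_invalid("iti_range lower bound must be >= 0")
  if (iti_range[2] < iti_range[1]) stop_invalid("iti_range must be ordered")
  set.seed(as.integer(seed))

  dirs <- seq(0, 360 - 360 / n_directions, by = 360 / n_directions)
  directions <- rep(dirs, times = n_repeats)
  laser <- rep(FALSE, length(directions))
  if (with_laser) {
    directions <- c(directions, directions)
    laser <- c(laser, rep(TRUE, length(laser)))
  }
  ord <- sample.int(length(directions))
  directions <- directions[ord]
  laser <- laser[ord]

  gaps <- runif(length(directions), iti_range[1], iti_range[2])
  onsets <- t_start + cumsum(c(0, (trial_dur + gaps)[-length(gaps)]))

  structure(list(trial_onsets = onsets, trial_duration = trial_dur,
                 directions = directions, laser_on = laser,
                 n_directions = n_directions, seed = as.integer(seed)),
            class = "grating_schedule")
}

#' Simulate a sparse-noise checkerboard movie
#'
#' Each square of each frame is independently white, black or gray with the
#' given probabilities. Defaults follow the standard sparse-noise protocol:
#' squares of 10 visual degrees, updated at 6 Hz, 1\% white and 1\% black.
#'
#' @param grid_shape integer length-2, squares as (rows, cols).
#' @param duration movie duration in seconds.
#' @param p_white,p_black probabilities of white (+1) and black (-1).
#' @param update_rate frame rate in Hz.
#' @param seed integer seed.
#' @param square_edge edge length of one square in visual degrees (metadata).
#'
#' @return An object of class `noise_movie`: list with `frame_times`,
#'   `frames` (array rows x cols x frames with values in \{-1, 0, 1\}),
#'   `square_edge` and `update_rate`.
#' @export
simulate_noise_movie <- function(grid_shape = c(10, 27), duration = 600,
                                 p_white = 0.01, p_black = 0.01,
                                 update_rate = 6, seed = 1L,
                                 square_edge = 10) {
  if (p_white < 0 || p_black < 0) stop_invalid("probabilities must be >= 0")
  if (p_white + p_black > 1) stop_invalid("p_white + p_black must be <= 1")
  set.seed(as.integer(seed))
  n_frames <- floor(duration * update_rate)
  vals <- sample(c(-1, 0, 1), size = prod(grid_shape) * n_frames,
                 replace = TRUE, prob = c(p_black, 1 - p_white - p_black, p_white))
  frames <- array(vals, dim = c(grid_shape[1], grid_shape[2], n_frames))
  structure(list(frame_times = (seq_len(n_frames) - 1L) / update_rate,
                 frames = frames, square_edge = square_edge,
                 update_rate = update_rate, seed = as.integer(seed)),
            class = "noise_movie")
}

#' Define a ground-truth unit for session synthesis
#'
#' Collects the generative parameters of one simulated unit: direction
#' tuning (preferred direction `theta_p`, width `sigma`, direction
#' selectivity `ds`, per-pupil-state peak amplitude `p_small`/`p_large` and
#' offsets), running-speed coupling, neuropil contamination `alpha_true`,
#' calcium kernel decay `kernel_tau`, and optional ON/OFF receptive fields.
#'
#' @param theta_p preferred direction, degrees in \[0, 360).
#' @param sigma tuning width (wrapped-Gaussian sigma), degrees, > 0.
#' @param ds direction selectivity (P-N)/(P+N), in \[0, 1\].
#' @param p_small,p_large peak response amplitude above offset per pupil state.
#' @param offset_small,offset_large additive offset per pupil state.
#' @param suppressed logical; TRUE inverts stimulus-driven gains.
#' @param run_coupling weight of the smoothed running-speed drive.
#' @param alpha_true neuropil contamination factor in \[0, 1.5\].
#' @param kernel_tau calcium decay time constant, seconds.
#' @param rf_on,rf_off optional ground-truth spatial fields (matrices matching
#'   the noise-movie grid) driving responses to sparse noise.
#'
#' @return An object of class `ground_truth_unit`.
#' @export
ground_truth_unit <- function(theta_p = 0, sigma = 35, ds = 0.5,
                              p_small = 1, p_large = 1,
                              offset_small = 0, offset_large = 0,
                              suppressed = FALSE, run_coupling = 0,
                              alpha_true = 0.7, kernel_tau = 0.5,
                              rf_on = NULL, rf_off = NULL) {
  if (sigma <= 0) stop_invalid("sigma must be > 0")
  if (ds < 0 || ds > 1) stop_invalid("ds must be in [0, 1]")
  if (alpha_true < 0 || alpha_true > 1.5)
    stop_invalid("alpha_true must be in [0, 1.5]")
  structure(list(theta_p = theta_p %% 360, sigma = sigma, ds = ds,
                 p_small = p_small, p_large = p_large,
                 offset_small = offset_small, offset_large = offset_large,
                 suppressed = suppressed, run_coupling = run_coupling,
                 alpha_true = alpha_true, kernel_tau = kernel_tau,
                 rf_on = rf_on, rf_off = rf_off),
            class = "ground_truth_unit")
}

#' Synthesize a full recording session with known ground truth
#'
#' Forward model matching the assumptions of the analysis pipeline. Each
#' unit's latent activity is a superposition of per-trial responses
#' (gain x exponential calcium kernel, gain drawn from the unit's tuning
#' curve at the trial's direction and pupil state), a running-speed drive
#' weighted by `run_coupling`, an optional receptive-field drive to the
#' sparse-noise movie, and a slow offset drift (amplitude `0.5 * noise_sd`).
#' Raw fluorescence is `F = latent + alpha_true * N + white noise` where `N`
#' is a shared slow neuropil contaminant; the red channel is
#' activity-independent. Simple spike streams (rate-modulated Poisson with
#' optional amplitude drift) are generated for simulated axons.
#'
#' @param units list of [ground_truth_unit()] objects (non-empty).
#' @param behavior a `behavior_traces` object covering all stimulus times.
#' @param gratings a `grating_schedule`.
#' @param noise optional `noise_movie` (required when any unit has RF fields);
#'   noise-movie responses are appended after the grating period.
#' @param noise_sd white-noise SD added to raw fluorescence.
#' @param seed integer seed.
#' @param gain_noise_sd multiplicative trial-gain jitter SD (relative).
#' @param n_axons number of simulated spiking axons.
#' @param axon_drift if TRUE, axon spike amplitudes and rates drift together.
#'
#' @return An object of class `synthetic_session`: behavior, stimuli, raw
#'   fluorescence triplets (`raw_F`, `raw_N`, `raw_red`; one column per
#'   unit), spike streams, and the `ground_truth` unit list.
#' @export
synthesize_session <- function(units, behavior, gratings, noise = NULL,
                               noise_sd = 0.1, seed = 1L,
                               gain_noise_sd = 0, n_axons = 0,
                               axon_drift = FALSE) {
  if (length(units) == 0) stop_invalid("units must be a non-empty list")
  stopifnot(inherits(behavior, "behavior_traces"),
            inherits(gratings, "grating_schedule"))
  t_end <- max(gratings$trial_onsets) + gratings$trial_duration
  if (max(behavior$times) < t_end)
    stop_invalid("behavior must cover all stimulus times")
  set.seed(as.integer(seed))

  times <- behavior$times
  dt <- behavior$dt
  n <- length(times)

  # Pupil state per trial via the same median rule used by the analysis.
  labels <- classify_trials_by_pupil(behavior, gratings)
  state <- labels$pupil_state

  # Shared slow neuropil contaminant.
  tau_np <- 30
  a <- exp(-dt / tau_np)
  w <- numeric(n); w[1] <- rnorm(1)
  eps <- rnorm(n - 1, 0, sqrt(1 - a^2))
  for (i in 2:n) w[i] <- a * w[i - 1] + eps[i - 1]
  raw_N_base <- 10 + 2 * w

  run_sm <- gaussian_smooth(behavior$running_speed, sigma_samples = 1 / dt)
  run_z <- if (sd(run_sm) > 0) (run_sm - mean(run_sm)) / sd(run_sm) else run_sm * 0

  onset_idx <- findInterval(gratings$trial_onsets, times)

  n_units <- length(units)
  raw_F <- matrix(0, n, n_units)
  raw_N <- matrix(0, n, n_units)
  raw_red <- matrix(0, n, n_units)

  for (u in seq_len(n_units)) {
    gu <- units[[u]]
    # Per-trial gains from the unit's tuning curve in the trial's state.
    pars_small <- tuning_params(theta_p = gu$theta_p, P = gu$p_small,
                                sigma = gu$sigma, DS = gu$ds,
                                offset = gu$offset_small)
    pars_large <- tuning_params(theta_p = gu$theta_p, P = gu$p_large,
                                sigma = gu$sigma, DS = gu$ds,
                                offset = gu$offset_large)
    gains <- ifelse(state == "small",
                    wrapped_double_gaussian(gratings$directions, pars_small),
                    wrapped_double_gaussian(gratings$directions, pars_large))
    if (gain_noise_sd > 0)
      gains <- gains * (1 + rnorm(length(gains), 0, gain_noise_sd))
    if (isTRUE(gu$suppressed)) gains <- -gains

    # Exponential calcium kernel, peak 1 at onset.
    klen <- max(2L, ceiling(5 * gu$kernel_tau / dt))
    kern <- exp(-(seq_len(klen) - 1L) * dt / gu$kernel_tau)

    latent <- numeric(n)
    for (i in seq_along(onset_idx)) {
      idx <- onset_idx[i]:min(n, onset_idx[i] + klen - 1L)
      latent[idx] <- latent[idx] + gains[i] * kern[seq_along(idx)]
    }
    latent <- latent + gu$run_coupling * run_z

    # Receptive-field drive to the sparse-noise movie, if configured.
    if (!is.null(gu$rf_on) && !is.null(noise)) {
      drive <- rf_linear_drive(noise, gu$rf_on, gu$rf_off)
      drive_t <- approx(noise$frame_times, drive, xout = times, rule = 2)$y
      conv <- stats::filter(drive_t, kern, sides = 1, method = "convolution")
      conv[is.na(conv)] <- 0
      latent <- latent + as.numeric(conv)
    }

    # Slow offset drift tied to the single noise knob.
    drift <- if (noise_sd > 0) {
      dv <- cumsum(rnorm(n, 0, noise_sd * 0.5 * sqrt(dt / 60)))
      dv - mean(dv)
    } else 0

    raw_N[, u] <- raw_N_base + rnorm(n, 0, noise_sd * 0.2)
    raw_F[, u] <- 5 + latent + drift + gu$alpha_true * raw_N[, u] +
      rnorm(n, 0, noise_sd)
    raw_red[, u] <- 3 + 0.5 * w + rnorm(n, 0, noise_sd * 0.5)
  }

  spikes <- list()
  if (n_axons > 0) {
    for (ax in seq_len(n_axons)) {
      base_rate <- runif(1, 2, 10)
      gain <- runif(1, 0, 0.5)
      rate <- pmax(0.1, base_rate * (1 + gain * run_z))
      if (axon_drift) rate <- rate * exp(-times / max(times))
      lambda <- rate * dt
      counts <- stats::rpois(n, lambda)
      st <- rep(times, counts) + runif(sum(counts), 0, dt)
      st <- sort(st)
      amp <- 100 + rnorm(length(st), 0, 3)
      if (axon_drift) amp <- amp * exp(-st / (2 * max(times)))
      spikes[[ax]] <- list(spike_times = st, amplitudes = amp)
    }
  }

  structure(list(behavior = behavior, gratings = gratings, noise = noise,
                 raw_F = raw_F, raw_N = raw_N, raw_red = raw_red,
                 spikes = spikes, ground_truth = units,
                 trial_pupil_state = state, seed = as.integer(seed)),
            class = "synthetic_session")
}

# Linear stimulus drive of a unit with ground-truth ON/OFF fields:
# sum over squares of w_on * 1{white} + w_off * 1{black} per frame.
rf_linear_drive <- function(noise, rf_on, rf_off = NULL) {
  fr <- noise$frames
  npix <- prod(dim(fr)[1:2])
  nf <- dim(fr)[3]
  m <- matrix(fr, npix, nf)
  on_v <- as.numeric(rf_on)
  drive <- as.numeric(crossprod(m == 1, on_v))
  if (!is.null(rf_off))
    drive <- drive + as.numeric(crossprod(m == -1, as.numeric(rf_off)))
  drive
}

#' Photoisomerization rate per cone
#'
#' Literal evaluation of the published estimate of photoisomerizations per
#' cone per second in the mouse eye,
#' \deqn{\Phi/\Delta T = \pi \, I \cdot 1500 \cdot \tau(\lambda)\,
#'   \frac{S_{pupil}}{S_{retina}} \, a_c(\lambda),}
#' with monitor irradiance \eqn{I} (cd/m^2), pre-photoreceptor transmission
#' \eqn{\tau(\lambda)}, pupil and retina areas (mm^2) and cone end-on
#' collecting area \eqn{a_c} (um^2). The formula is evaluated literally;
#' see the methods vignette for a note on its absolute scale.
#'
#' @param irradiance_I monitor irradiance, cd/m^2 (typically ~83).
#' @param tau_lambda transmission of pre-photoreceptor media (typically 0.7).
#' @param s_pupil pupil area, mm^2 (0.1-3.2 across pupil sizes).
#' @param s_retina retinal area, mm^2 (typically 18).
#' @param a_c cone end-on collecting area, um^2 (typically 1).
#' @param factor_1500 the printed constant (default 1500).
#'
#' @return Photoisomerization rate (R/cone/s under the printed formula).
#' @export
photoisomerization_rate <- function(irradiance_I = 83, tau_lambda = 0.7,
                                    s_pupil = 1, s_retina = 18, a_c = 1,
                                    factor_1500 = 1500) {
  vals <- c(irradiance_I, tau_lambda, s_retina, a_c, factor_1500)
  if (any(vals <= 0) || s_pupil < 0)
    stop_invalid("all light-model parameters must be positive")
  pi * irradiance_I * factor_1500 * tau_lambda * (s_pupil / s_retina) * a_c
}
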