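# Shared fixture builders: everything is generated in code under fixed
# seeds; no data files.

# Smoothed autocorrelated noise resembling a quiescent calcium trace.
ar_noise <- function(n, ar = 0.9, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as.numeric(arima.sim(list(ar = ar), n)) * sd * sqrt(1 - ar^2)
}

# Compact grating schedule + time grid that fits a short trace.
quick_schedule <- function(n_directions = 4, n_repeats = 4, seed = 1,
                           dt = 0.133, tail = 20) {
  sch <- simulate_grating_schedule(n_directions, n_repeats, trial_dur = 2,
                                   iti_range = c(3, 6), seed = seed,
                                   t_start = 5)
  times <- seq(0, max(sch$trial_onsets) + tail, by = dt)
  list(schedule = sch, times = times, dt = dt)
}

# Forward model of the kernel/scaling fit: gains convolved with an
# exponential kernel on the trace grid.
forward_trace <- function(schedule, times, gains, tau = 0.5, noise_sd = 0,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dt <- median(diff(times))
  n <- length(times)
  klen <- ceiling(5 * tau / dt)
  kern <- exp(-(seq_len(klen) - 1) * dt / tau)
  o <- findInterval(schedule$trial_onsets, times)
  y <- numeric(n)
  for (i in seq_along(o)) {
    idx <- o[i]:min(n, o[i] + klen - 1)
    y[idx] <- y[idx] + gains[i] * kern[seq_along(idx)]
  }
  if (noise_sd > 0) y <- y + rnorm(n, 0, noise_sd)
  y
}

# Trial amplitudes drawn from a wrapped double-Gaussian tuning curve.
tuning_amplitudes <- function(theta_p, sigma, DS, P, offset, directions,
                              noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pars <- tuning_params(theta_p, P, sigma, DS, offset)
  wrapped_double_gaussian(directions, pars) +
    rnorm(length(directions), 0, noise_sd)
}

# Small sparse-noise movie + a unit with Gaussian ON/OFF fields driving it.
rf_ground_truth <- function(grid = c(8, 8), cy = 3, cx = 5, w = 1.2,
                            on_gain = 1, off_gain = 0.4) {
  g <- outer(dnorm(seq_len(grid[1]), cy, w), dnorm(seq_len(grid[2]), cx, w))
  g <- g / max(g)
  list(on = on_gain * g, off = off_gain * g)
}

rf_response <- function(noise, rf, lag = 2, noise_sd = NULL, run_gain = 0,
                        seed = 1) {
  set.seed(seed)
  nf <- dim(noise$frames)[3]
  S <- matrix(noise$frames, prod(dim(noise$frames)[1:2]), nf)
  drive <- as.numeric(crossprod(S == 1, as.numeric(rf$on))) +
    as.numeric(crossprod(S == -1, as.numeric(rf$off)))
  y <- c(rep(0, lag), drive[seq_len(nf - lag)])
  run <- as.numeric(arima.sim(list(ar = 0.98), nf))
  run <- run / sd(run)
  if (is.null(noise_sd)) noise_sd <- sd(y) / 2
  list(y = y + run_gain * run + rnorm(nf, 0, noise_sd), run = run,
       drive = y)
}

# Reduced pipeline configuration used by smoke and determinism tests.
small_config <- function(seed = 5) {
  session_config(n_units = 2, n_repeats = 4, n_directions = 8,
                 duration = 420, n_axons = 1, seed = seed,
                 n_shifts_responsiveness = 50, n_shifts = 200,
                 n_perm_selectivity = 200, n_perm_modulation = 50)
}
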