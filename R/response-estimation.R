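# Single-trial response estimation for drifting gratings: the alternating
# kernel / per-trial-scaling linear-model fit, its circular-shift
# responsiveness test, pupil-state trial labels, and spike-count rates.
#
# The two alternating least-squares steps are solved through their normal
# equations built directly from the trial-window structure: because every
# kernel regressor is a shifted copy of the same window, X'X is a banded
# matrix determined by the trial-onset offsets, and X'y is a gather of the
# trace over trial windows. This makes each refit cheap enough for the
# thousands of refits the circular-shift responsiveness null requires.

# Onset sample index of each trial on the trace grid.
trial_onset_index <- function(times, onsets) {
  idx <- findInterval(onsets, times)
  if (any(idx < 1) || any(onsets > max(times)))
    stop_invalid("schedule trials outside trace extent")
  idx
}

# Precompute the fit geometry for one (schedule, time grid) combination:
# trial-window sample indices and the list of overlapping trial pairs.
ks_context <- function(schedule, times, kernel_dur = 15) {
  dt <- median(diff(times))
  n <- length(times)
  klen <- round(kernel_dur / dt)
  o <- trial_onset_index(times, schedule$trial_onsets)
  if (max(o) + klen - 1L > n)
    stop_invalid("trace must extend at least kernel_dur past the last onset")
  n_tr <- length(o)
  idx <- outer(seq_len(klen) - 1L, o, `+`)
  pr_i <- integer(0); pr_m <- integer(0); pr_d <- integer(0)
  for (i in seq_len(n_tr)) {
    m <- which(abs(o - o[i]) < klen & seq_len(n_tr) != i)
    pr_i <- c(pr_i, rep(i, length(m)))
    pr_m <- c(pr_m, m)
    pr_d <- c(pr_d, o[i] - o[m])
  }
  list(n = n, klen = klen, n_trials = n_tr, onset_idx = o, idx = idx,
       dt = dt, pr_i = pr_i, pr_m = pr_m, pr_d = pr_d)
}

# One full alternating fit on a prebuilt context.
ks_fit <- function(y, ctx, tol = 1e-4, max_iter = 100) {
  klen <- ctx$klen; n_tr <- ctx$n_trials; n <- ctx$n
  Yw <- matrix(y[ctx$idx], klen, n_tr)
  ysum <- sum(y)

  scalings <- rep(1, n_tr)
  kernel <- numeric(klen)
  intercept <- 0
  mse_path <- numeric(0)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    # (i) kernel given scalings: banded normal equations + intercept
    G <- diag(sum(scalings^2), klen)
    if (length(ctx$pr_d)) {
      w <- rowsum(scalings[ctx$pr_i] * scalings[ctx$pr_m], ctx$pr_d)
      dvals <- as.integer(rownames(w))
      for (q in seq_along(dvals)) {
        d <- dvals[q]
        j <- seq.int(max(1L, 1L - d), min(klen, klen - d))
        ij <- cbind(j, j + d)
        G[ij] <- G[ij] + w[q]
      }
    }
    ssum <- sum(scalings)
    A <- rbind(c(n, rep(ssum, klen)), cbind(ssum, G))
    diag(A) <- diag(A) + 1e-10
    ck <- unname(solve(A, c(ysum, as.numeric(Yw %*% scalings))))
    kernel <- ck[-1]

    # (ii) scalings given kernel: kernel-autocorrelation normal equations
    G2 <- diag(sum(kernel^2), n_tr)
    if (length(ctx$pr_d)) {
      dabs <- abs(ctx$pr_d)
      rho <- vapply(sort(unique(dabs)), function(d) {
        sum(kernel[seq_len(klen - d)] * kernel[seq.int(1L + d, klen)])
      }, numeric(1))
      names(rho) <- sort(unique(dabs))
      G2[cbind(ctx$pr_i, ctx$pr_m)] <- rho[as.character(dabs)]
    }
    ksum <- sum(kernel)
    A2 <- rbind(c(n, rep(ksum, n_tr)), cbind(ksum, G2))
    diag(A2) <- diag(A2) + 1e-10
    cs <- unname(solve(A2, c(ysum, as.numeric(crossprod(Yw, kernel)))))
    intercept <- cs[1]
    new_scalings <- cs[-1]

    pred <- rep(intercept, n)
    for (i in seq_len(n_tr))
      pred[ctx$idx[, i]] <- pred[ctx$idx[, i]] + new_scalings[i] * kernel
    mse_path <- c(mse_path, mean((y - pred)^2))

    rel <- max(abs(new_scalings - scalings) / pmax(abs(scalings), 1e-8))
    scalings <- new_scalings
    if (rel < tol) { converged <- TRUE; break }
  }
  peak <- max(abs(kernel))
  if (peak > 0) {
    kernel <- kernel / peak
    scalings <- scalings * peak
  }
  mse <- mse_path[length(mse_path)]
  r2 <- 1 - mse * n / sum((y - mean(y))^2)
  p <- klen + n_tr
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  structure(list(kernel = kernel, scalings = scalings, intercept = intercept,
                 adjusted_r2 = adj_r2, mse = mse, mse_path = mse_path,
                 converged = converged, n_iter = it, klen = klen,
                 dt = ctx$dt),
            class = "kernel_response_model")
}

#' Iterative kernel / trial-scaling fit of grating responses
#'
#' Estimates single-trial response amplitudes from a calcium trace by
#' alternating two linear least-squares steps: (i) fit one temporal
#' response kernel of length 15 s to all trials given the current per-trial
#' scaling factors (initially 1), with overlapping trial windows superposed
#' additively; (ii) fit a scaling factor per trial given the kernel. After
#' each iteration the kernel is renormalized to unit peak magnitude and the
#' scalings rescaled to preserve the product. Iterations stop when the
#' maximum relative change of the scalings drops below `tol` or after
#' `max_iter` iterations. This corrects for slow calcium decay spilling
#' into subsequent trials, which stimulus-triggered averages cannot.
#'
#' @param dff delta-F/F trace.
#' @param schedule a `grating_schedule`.
#' @param times sample times of `dff` in seconds; the trace must extend at
#'   least the kernel duration past the last trial onset.
#' @param kernel_dur kernel duration in seconds (default 15).
#' @param tol relative-change convergence tolerance.
#' @param max_iter maximum number of alternations.
#'
#' @return An object of class `kernel_response_model`: list with `kernel`
#'   (unit peak magnitude), `scalings` (one per trial), `intercept`,
#'   `adjusted_r2`, `mse`, `mse_path`, `converged`, `n_iter`.
#' @export
fit_kernel_scaling <- function(dff, schedule, times, kernel_dur = 15,
                               tol = 1e-4, max_iter = 100) {
  if (sd(dff) == 0) stop_degenerate("zero-variance trace")
  ctx <- ks_context(schedule, times, kernel_dur)
  ks_fit(dff, ctx, tol = tol, max_iter = max_iter)
}

#' Circular-shift responsiveness test for the kernel/scaling fit
#'
#' Refits the kernel/scaling model after circularly shifting the trace
#' against the stimulus times `n_shifts` times (shifts of at least
#' `min_shift` seconds) and returns the one-sided p-value: the fraction of
#' null MSEs that are at or below the measured MSE. A unit is considered
#' responsive when the measured MSE falls below the null 95\% confidence
#' band, i.e. `p < 0.025`.
#'
#' @param dff delta-F/F trace.
#' @param schedule a `grating_schedule`.
#' @param times sample times in seconds.
#' @param n_shifts number of circular shifts (>= 20; default 200).
#' @param seed integer seed.
#' @param min_shift minimum shift in seconds.
#' @param max_iter alternation cap for all fits.
#'
#' @return List with `p`, `responsive` (p < 0.025), `mse_observed`,
#'   `model` (the fit to the unshifted trace).
#' @export
test_responsiveness <- function(dff, schedule, times, n_shifts = 200,
                                seed = 1L, min_shift = 30, max_iter = 20) {
  if (n_shifts < 20) stop_invalid("n_shifts must be >= 20")
  if (sd(dff) == 0) stop_degenerate("zero-variance trace")
  set.seed(as.integer(seed))
  n <- length(dff)
  ctx <- ks_context(schedule, times)
  model <- ks_fit(dff, ctx, max_iter = max_iter)
  shifts <- random_shifts(n, n_shifts, round(min_shift / ctx$dt))
  null_mse <- vapply(shifts, function(s) {
    ys <- dff[c((s + 1):n, 1:s)]
    ks_fit(ys, ctx, max_iter = max_iter)$mse
  }, numeric(1))
  p <- mean(null_mse <= model$mse)
  list(p = p, responsive = p < 0.025, mse_observed = model$mse, model = model)
}

#' Label trials by pupil state
#'
#' The pupil trace (blink samples excluded) is thresholded at its session
#' median; a trial is labeled "small" if strictly more than half of its
#' non-blink samples lie below the threshold, and "large" otherwise. Trials
#' whose samples are all blink-masked get an NA label and are excluded
#' downstream.
#'
#' @param behavior a `behavior_traces` object (or list with `times`,
#'   `pupil_area`, `blink_mask`).
#' @param schedule a `grating_schedule`.
#'
#' @return List of class `trial_labels` with `pupil_state` (character
#'   "small"/"large"/NA per trial), `laser_state` and `threshold`.
#' @export
classify_trials_by_pupil <- function(behavior, schedule) {
  pupil <- behavior$pupil_area
  pupil[behavior$blink_mask] <- NA_real_
  thr <- median(pupil, na.rm = TRUE)
  onsets <- schedule$trial_onsets
  offs <- onsets + schedule$trial_duration
  state <- vapply(seq_along(onsets), function(i) {
    sel <- behavior$times >= onsets[i] & behavior$times < offs[i]
    v <- pupil[sel]
    v <- v[is.finite(v)]
    if (length(v) == 0) return(NA_character_)
    if (sum(v < thr) > length(v) / 2) "small" else "large"
  }, character(1))
  structure(list(pupil_state = state,
                 laser_state = schedule$laser_on, threshold = thr),
            class = "trial_labels")
}

#' Per-trial firing rates from a spike train
#'
#' Rate of trial i is the spike count in the half-open interval
#' \[onset_i, offset_i) divided by the trial duration.
#'
#' @param spike_times spike times in seconds.
#' @param schedule a `grating_schedule`.
#'
#' @return Numeric vector of rates (spikes/s), one per trial.
#' @export
firing_rate_responses <- function(spike_times, schedule) {
  onsets <- schedule$trial_onsets
  offs <- onsets + schedule$trial_duration
  vapply(seq_along(onsets), function(i) {
    sum(spike_times >= onsets[i] & spike_times < offs[i]) /
      schedule$trial_duration
  }, numeric(1))
}
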