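# Neuropil-corrected delta-F/F preprocessing for two-photon traces:
# moving-percentile baselines, neuropil factor estimation, red-channel
# motion regression, duplicate-unit removal and transient-based exclusion.

#' Moving-percentile baseline of a fluorescence trace
#'
#' Each output sample is the `pct`-th percentile of the trace within a
#' centered moving window (default 180 s, 8th percentile — the standard
#' slow-baseline estimator for calcium traces). Windows are truncated at
#' the trace edges, not padded, so the baseline is defined everywhere.
#'
#' @param trace numeric fluorescence trace (finite values).
#' @param dt sample interval in seconds.
#' @param window window length in seconds (>= 3 samples).
#' @param pct percentile in \[0, 100\].
#'
#' @return Numeric baseline trace of the same length.
#' @export
percentile_baseline <- function(trace, dt, window = 180, pct = 8) {
  if (length(trace) == 0) stop_invalid("empty trace")
  w <- round(window / dt)
  if (w < 3) stop_invalid("window must span at least 3 samples")
  half <- floor(w / 2)
  .moving_percentile_cpp(as.numeric(trace), as.integer(half), pct / 100)
}

#' Estimate the neuropil contamination factor alpha
#'
#' High-pass versions of the somatic and neuropil traces are formed by
#' subtracting their moving 8th-percentile baselines; alpha is the slope of
#' a linear fit of the high-passed neuropil to the high-passed somatic
#' trace restricted to samples where the somatic trace is in its lower half
#' (quiescent, non-spiking epochs), refit once after discarding the 5\% of
#' points with the largest absolute residuals. The estimate is clipped to
#' \[0, 1.5\].
#'
#' @param F somatic/bouton fluorescence trace.
#' @param N neuropil fluorescence trace (same length).
#' @param dt sample interval in seconds.
#' @param window,pct baseline parameters passed to [percentile_baseline()].
#'
#' @return List with `alpha` and `degenerate` (TRUE when N has no variance,
#'   in which case alpha is 0 and a warning is issued).
#' @export
estimate_neuropil_alpha <- function(F, N, dt, window = 180, pct = 8) {
  if (length(F) != length(N)) stop_invalid("F and N must have equal length")
  if (sd(N) == 0) {
    warning("neuropil trace has zero variance; alpha set to 0")
    return(list(alpha = 0, degenerate = TRUE))
  }
  Ff <- F - percentile_baseline(F, dt, window, pct)
  Nf <- N - percentile_baseline(N, dt, window, pct)
  low <- Ff <= quantile(Ff, 0.5)
  fit <- lm.fit(cbind(1, Nf[low]), Ff[low])
  res <- abs(fit$residuals)
  keep <- res <= quantile(res, 0.95)
  x <- Nf[low][keep]
  if (sd(x) == 0) {
    warning("neuropil trace has zero variance in the fit mask; alpha set to 0")
    return(list(alpha = 0, degenerate = TRUE))
  }
  fit2 <- lm.fit(cbind(1, x), Ff[low][keep])
  alpha <- unname(fit2$coefficients[2])
  list(alpha = min(1.5, max(0, alpha)), degenerate = FALSE)
}

#' Neuropil-corrected delta-F/F
#'
#' Subtracts the scaled neuropil trace, `F_c = F - alpha * N`, estimates the
#' slow corrected baseline `F_c0` with the moving 8th percentile, and
#' returns `dff = (F_c - F_c0) / max(1, mean(F_c0))`. The `max(1, .)` guard
#' prevents noise blow-up for dim units.
#'
#' @param F somatic fluorescence trace.
#' @param N neuropil trace.
#' @param alpha neuropil factor (from [estimate_neuropil_alpha()] or known).
#' @param dt sample interval in seconds.
#' @param window,pct baseline parameters.
#'
#' @return An object of class `corrected_trace`: list with `dff`, `alpha`,
#'   `f0` (corrected baseline), `excluded` (FALSE here) and
#'   `exclusion_reason` (NA).
#' @export
compute_dff <- function(F, N, alpha, dt, window = 180, pct = 8) {
  if (length(F) != length(N)) stop_invalid("F and N must have equal length")
  if (alpha < 0) stop_invalid("alpha must be >= 0")
  Fc <- F - alpha * N
  Fc0 <- percentile_baseline(Fc, dt, window, pct)
  dff <- (Fc - Fc0) / max(1, mean(Fc0))
  structure(list(dff = dff, alpha = alpha, f0 = Fc0, dt = dt,
                 excluded = FALSE, exclusion_reason = NA_character_),
            class = "corrected_trace")
}

#' Regress brain-motion artifacts out of delta-F/F using the red channel
#'
#' The activity-independent red trace is drift-removed (moving 8th
#' percentile subtraction), median-filtered in a 10-s moving window, and
#' its least-squares projection is subtracted from the calcium trace. A red
#' trace with zero variance after processing leaves the input unchanged.
#'
#' @param dff delta-F/F trace.
#' @param red red-channel fluorescence trace (same length).
#' @param dt sample interval in seconds.
#' @param median_window median-filter window in seconds (default 10).
#'
#' @return Corrected delta-F/F vector.
#' @export
regress_out_red <- function(dff, red, dt, median_window = 10) {
  if (length(dff) != length(red)) stop_invalid("dff and red length mismatch")
  if (sd(red) == 0) return(dff)
  r <- red - percentile_baseline(red, dt)
  k <- round(median_window / dt)
  if (k %% 2 == 0) k <- k + 1
  if (k >= 3 && k <= length(r)) r <- as.numeric(stats::runmed(r, k))
  if (sd(r) == 0) return(dff)
  beta <- cov(dff, r) / var(r)
  dff - beta * (r - mean(r))
}

#' Remove duplicate units detected in adjacent imaging planes
#'
#' The same neuron or bouton can be segmented in two neighboring planes.
#' For every pair of units in adjacent planes whose centroids are within
#' `max_dist` and whose 5-sample median-filtered traces have Pearson
#' correlation above `rho_threshold` (0.4 for somata, 0.5 for boutons),
#' only the member with the higher signal-to-noise ratio is kept. The
#' operation is idempotent.
#'
#' @param traces list of numeric dff traces (or `corrected_trace` objects).
#' @param positions matrix (n x 2) of unit centroids in microns.
#' @param plane_ids integer plane index per unit.
#' @param rho_threshold correlation threshold in (0, 1).
#' @param snr numeric per-unit signal-to-noise score.
#' @param max_dist centroid distance defining "close" pairs (microns).
#'
#' @return Logical keep mask, one entry per unit.
#' @export
deduplicate_units <- function(traces, positions, plane_ids,
                              rho_threshold = 0.5, snr, max_dist = 5) {
  if (rho_threshold <= 0 || rho_threshold >= 1)
    stop_invalid("rho_threshold must be in (0, 1)")
  mat <- lapply(traces, function(tr) {
    v <- if (inherits(tr, "corrected_trace")) tr$dff else tr
    as.numeric(stats::runmed(v, 5))
  })
  n <- length(mat)
  keep <- rep(TRUE, n)
  if (n < 2) return(keep)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(plane_ids[i] - plane_ids[j]) != 1) next
      d <- sqrt(sum((positions[i, ] - positions[j, ])^2))
      if (d >= max_dist) next
      if (sd(mat[[i]]) == 0 || sd(mat[[j]]) == 0) next
      if (cor(mat[[i]], mat[[j]]) > rho_threshold) {
        drop <- if (snr[i] >= snr[j]) j else i
        keep[drop] <- FALSE
      }
    }
  }
  keep
}

#' Flag units with abnormally long calcium transients
#'
#' Detects contiguous excursions above 3 robust SDs (1.4826 x MAD about
#' zero) and returns TRUE when any excursion lasts longer than
#' `max_duration` (default 25 s) — such units are removed from analysis.
#'
#' @param dff delta-F/F trace.
#' @param dt sample interval in seconds.
#' @param max_duration maximum allowed transient duration in seconds.
#' @param n_sd threshold in robust SDs.
#'
#' @return Logical scalar.
#' @export
flag_long_transients <- function(dff, dt, max_duration = 25, n_sd = 3) {
  s <- mad(dff, center = 0)
  if (s == 0) return(FALSE)
  above <- dff > n_sd * s
  r <- rle(above)
  any(r$values & r$lengths * dt > max_duration)
}

#' Preprocess one raw fluorescence triplet into delta-F/F
#'
#' Convenience wrapper chaining [estimate_neuropil_alpha()],
#' [compute_dff()], [regress_out_red()] and [flag_long_transients()].
#'
#' @param F,N,red raw fluorescence traces of one unit.
#' @param dt sample interval in seconds.
#'
#' @return A `corrected_trace` with fields `dff`, `alpha`, `excluded`,
#'   `exclusion_reason`.
#' @export
preprocess_unit <- function(F, N, red, dt) {
  a <- estimate_neuropil_alpha(F, N, dt)
  ct <- compute_dff(F, N, a$alpha, dt)
  ct$dff <- regress_out_red(ct$dff, red, dt)
  if (flag_long_transients(ct$dff, dt)) {
    ct$excluded <- TRUE
    ct$exclusion_reason <- "long_transient"
  }
  ct
}
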