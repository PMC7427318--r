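# Quality control for optic-tract spike streams: rate binning,
# mass-amplitude drift filtering, amplitude-rate correlation exclusion,
# and waveform-stability scoring.

#' Bin a spike train into a firing-rate trace
#'
#' Counts per bin divided by the bin width; the total spike count within
#' the extent is conserved exactly. The conventional bin width of 133 ms
#' matches the ~7.5 Hz sampling of calcium imaging.
#'
#' @param spike_times spike times in seconds.
#' @param bin_width bin width in seconds (default 0.133).
#' @param extent numeric length-2 covering all spikes, (start, end).
#'
#' @return List with `times` (bin centers) and `rate` (spikes/s).
#' @export
bin_spike_rate <- function(spike_times, bin_width = 0.133,
                           extent = c(0, if (length(spike_times)) max(spike_times) + bin_width else bin_width)) {
  edges <- seq(extent[1], extent[2] + bin_width - 1e-12, by = bin_width)
  counts <- if (length(spike_times) == 0) rep(0L, length(edges) - 1) else {
    tabulate(findInterval(spike_times, edges, left.open = FALSE,
                          rightmost.closed = FALSE),
             nbins = length(edges) - 1)
  }
  list(times = head(edges, -1) + bin_width / 2, rate = counts / bin_width,
       counts = counts)
}

# Kernel-density modal amplitude (Silverman bandwidth).
density_mode <- function(x) {
  if (length(x) < 2 || sd(x) == 0) return(x[1])
  d <- stats::density(x, bw = "nrd0")
  d$x[which.max(d$y)]
}

#' Remove low-amplitude contaminant spikes by the mass-amplitude rule
#'
#' Spikes are binned in bins of `bin_size` spikes (in time order). For each
#' bin the most frequent ("mass") amplitude is estimated by kernel density;
#' the mass-amplitude vector is smoothed with a 3-bin moving average. The
#' SD of the amplitude distribution is estimated from spikes above their
#' local mass amplitude by a half-Gaussian fit, and spikes with amplitudes
#' below mass - `k_sd` * SD are discarded. Removal is monotone in `k_sd`.
#'
#' @param spike_times spike times (seconds, ascending).
#' @param amplitudes spike amplitudes (positive).
#' @param bin_size spikes per bin (default 100).
#' @param k_sd cut in SDs below the mass amplitude (in \[5, 20\]).
#'
#' @return An object of class `qc_report`: list with `keep_mask`,
#'   `mass_amplitude` (per spike, smoothed), `sd_est`, `n_removed`.
#' @export
mass_amplitude_filter <- function(spike_times, amplitudes, bin_size = 100,
                                  k_sd = 10) {
  if (k_sd < 5 || k_sd > 20) stop_invalid("k_sd must be in [5, 20]")
  n <- length(amplitudes)
  if (n == 0) stop_invalid("no spikes")
  bin <- pmin(((seq_len(n) - 1L) %/% bin_size) + 1L, max(1L, n %/% bin_size))
  n_bins <- max(bin)
  mass <- vapply(seq_len(n_bins), function(b) density_mode(amplitudes[bin == b]),
                 numeric(1))
  if (n_bins >= 3) {
    sm <- stats::filter(mass, rep(1 / 3, 3), sides = 2)
    sm[1] <- mean(mass[1:2]); sm[n_bins] <- mean(mass[(n_bins - 1):n_bins])
    mass <- as.numeric(sm)
  }
  mass_per_spike <- mass[bin]
  dev <- amplitudes - mass_per_spike
  pos <- dev[dev > 0]
  sd_est <- if (length(pos) > 1) sqrt(mean(pos^2)) else sd(amplitudes)
  if (!is.finite(sd_est) || sd_est == 0) sd_est <- 0
  keep <- amplitudes >= mass_per_spike - k_sd * sd_est
  structure(list(keep_mask = keep, mass_amplitude = mass_per_spike,
                 sd_est = sd_est, n_removed = sum(!keep)),
            class = "qc_report")
}

#' Shift-test for correlation between spike amplitude and firing rate
#'
#' A unit whose spike amplitude co-varies with its firing rate is likely
#' contaminated by electrode drift and is excluded. Spikes are binned in
#' time; per-bin mean amplitude is tested against per-bin rate with the
#' circular-shift test. Constant amplitudes make the correlation undefined;
#' the unit is then retained with a note.
#'
#' @param spike_times spike times in seconds (>= 100 spikes).
#' @param amplitudes spike amplitudes.
#' @param bin_width time-bin width in seconds (default 10).
#' @param n_shifts circular shifts (default 500).
#' @param seed integer seed.
#'
#' @return List with `p` (NA when undefined), `r`, `excluded`, `reason`.
#' @export
amplitude_rate_drift_check <- function(spike_times, amplitudes,
                                       bin_width = 10, n_shifts = 500,
                                       seed = 1L) {
  if (length(spike_times) < 100) stop_invalid("need at least 100 spikes")
  extent <- c(min(spike_times), max(spike_times) + 1e-9)
  edges <- seq(extent[1], extent[2] + bin_width, by = bin_width)
  bin <- findInterval(spike_times, edges, rightmost.closed = TRUE)
  n_bins <- length(edges) - 1
  rate <- tabulate(bin, nbins = n_bins) / bin_width
  amp <- vapply(seq_len(n_bins), function(b) {
    v <- amplitudes[bin == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  ok <- is.finite(amp)
  if (sd(amplitudes) == 0 || sd(amp[ok]) == 0 || sum(ok) < 10)
    return(list(p = NA_real_, r = NA_real_, excluded = FALSE,
                reason = "constant amplitude: correlation undefined"))
  res <- shift_test(rate[ok], amp[ok], n_shifts = n_shifts,
                    min_shift = 5 * bin_width, dt = bin_width, seed = seed,
                    min_samples = 30)
  list(p = res$p, r = res$r, excluded = res$significant,
       reason = if (res$significant) "amplitude-rate correlation" else NA_character_)
}

#' Waveform stability between running and stationary episodes
#'
#' Pearson correlation of the concatenated multi-channel mean waveforms
#' from a running episode and a nearby stationary episode; a change in
#' waveform (score below `threshold`, default 0.95) points to electrode
#' movement and flags the unit.
#'
#' @param waveform_running,waveform_stationary numeric vectors or matrices
#'   (samples x channels) with equal sample counts.
#' @param threshold flagging threshold on the correlation.
#'
#' @return List with `score` and `flagged`.
#' @export
waveform_stability <- function(waveform_running, waveform_stationary,
                               threshold = 0.95) {
  a <- as.numeric(waveform_running); b <- as.numeric(waveform_stationary)
  if (length(a) != length(b)) stop_invalid("waveforms must match in size")
  if (sd(a) == 0 || sd(b) == 0)
    stop_degenerate("zero-variance waveform: score undefined")
  score <- cor(a, b)
  list(score = score, flagged = score < threshold)
}

#' Run the full spike-stream quality-control chain
#'
#' Applies [mass_amplitude_filter()] then [amplitude_rate_drift_check()]
#' on the retained spikes and assembles a per-unit report.
#'
#' @param spike_times,amplitudes one unit's spike stream.
#' @param k_sd mass-amplitude cut (SDs).
#' @param seed integer seed.
#'
#' @return List with `keep_mask`, `kept_fraction`, `amp_rate_p`,
#'   `excluded`, `reasons`.
#' @export
spike_qc_chain <- function(spike_times, amplitudes, k_sd = 10, seed = 1L) {
  maf <- mass_amplitude_filter(spike_times, amplitudes, k_sd = k_sd)
  st <- spike_times[maf$keep_mask]
  am <- amplitudes[maf$keep_mask]
  drift <- if (length(st) >= 100)
    amplitude_rate_drift_check(st, am, seed = seed)
  else list(p = NA_real_, excluded = FALSE, reason = "too few spikes")
  reasons <- character(0)
  if (isTRUE(drift$excluded)) reasons <- c(reasons, drift$reason)
  list(keep_mask = maf$keep_mask,
       kept_fraction = mean(maf$keep_mask),
       amp_rate_p = drift$p,
       excluded = isTRUE(drift$excluded),
       reasons = reasons)
}
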