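# Trace-level behavioral post-processing shared by all analyses.

#' Clean a pupil-size trace
#'
#' Applies a 5-sample moving median and sets blink-masked samples to NA;
#' masked samples stay missing and are excluded from downstream statistics
#' rather than interpolated.
#'
#' @param area pupil area trace (arbitrary units).
#' @param blink_mask logical blink flag per sample.
#'
#' @return Numeric trace with blinks as NA.
#' @export
clean_pupil <- function(area, blink_mask = rep(FALSE, length(area))) {
  if (all(blink_mask)) stop_invalid("all samples blink-masked: empty trace")
  v <- area
  v[blink_mask] <- NA_real_
  # median-filter on observed samples only, then reinstate the NA mask
  obs <- which(!blink_mask)
  if (length(obs) >= 3) {
    k <- min(5L, length(obs) - (1 - length(obs) %% 2))
    if (k >= 3) v[obs] <- as.numeric(stats::runmed(area[obs], k))
  }
  v[blink_mask] <- NA_real_
  v
}

#' Running speed from rotary-encoder counts
#'
#' Converts encoder pulse counts to linear speed,
#' `speed = (d counts / counts_per_rotation) * circumference / dt`,
#' followed by a light low-pass smoothing (0.5-s Gaussian).
#'
#' @param encoder_counts cumulative pulse counts per sample.
#' @param counts_per_rotation pulses per full wheel rotation (e.g. 1024).
#' @param wheel_circumference wheel circumference in cm.
#' @param dt sample interval in seconds.
#' @param smooth_sigma Gaussian smoothing SD in seconds (0 disables).
#'
#' @return Numeric speed trace (cm/s).
#' @export
running_speed_from_counts <- function(encoder_counts, counts_per_rotation,
                                      wheel_circumference, dt,
                                      smooth_sigma = 0.5) {
  if (dt <= 0) stop_invalid("dt must be positive")
  if (counts_per_rotation <= 0 || wheel_circumference <= 0)
    stop_invalid("calibration constants must be positive")
  d <- c(0, diff(encoder_counts))
  speed <- d / counts_per_rotation * wheel_circumference / dt
  if (smooth_sigma > 0) speed <- gaussian_smooth(speed, smooth_sigma / dt)
  speed
}
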