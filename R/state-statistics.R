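# Correlation and resampling statistics for behavioral-state analyses:
# Gaussian smoothing/alignment, circular-shift null tests, cross-
# correlograms with null bands, Fisher's combined test, a generic
# permutation engine, and a circular paired test of mean direction.

# Gaussian convolution with kernel truncated at +/- 4 sigma and
# renormalized at the edges (and across NA gaps).
gaussian_smooth <- function(x, sigma_samples) {
  if (sigma_samples <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma_samples))
  k <- dnorm(seq(-half, half), sd = sigma_samples)
  n <- length(x)
  ok <- as.numeric(is.finite(x))
  x0 <- ifelse(is.finite(x), x, 0)
  num <- stats::filter(c(rep(0, half), x0, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), ok, rep(0, half)), k, sides = 2)
  out <- as.numeric(num[(half + 1):(half + n)]) /
    as.numeric(den[(half + 1):(half + n)])
  out[den[(half + 1):(half + n)] == 0] <- NA_real_
  out
}

#' Interpolate a behavioral trace onto a target time grid and smooth it
#'
#' Linearly interpolates `trace` from `times` onto `target_times`, then
#' convolves with a Gaussian window (default sigma 1 s, the standard choice
#' for comparing behavioral traces with calcium signals). The kernel is
#' truncated at +/- 4 sigma and renormalized at the edges so means are
#' preserved. NA samples (e.g. blinks) are excluded from the kernel
#' normalization rather than propagated wholesale.
#'
#' @param trace numeric source trace.
#' @param times source sample times (seconds, increasing).
#' @param target_times target grid; must lie within the source extent.
#' @param sigma smoothing SD in seconds; 0 disables smoothing.
#'
#' @return Numeric vector on `target_times`.
#' @export
smooth_and_align <- function(trace, times, target_times, sigma = 1) {
  if (length(trace) != length(times)) stop_invalid("trace/times length mismatch")
  if (min(target_times) < min(times) - 1e-9 ||
      max(target_times) > max(times) + 1e-9)
    stop_invalid("target_times outside source extent (no extrapolation)")
  ok <- is.finite(trace)
  y <- approx(times[ok], trace[ok], xout = target_times, rule = 2)$y
  if (sigma > 0 && length(target_times) > 1) {
    dt <- median(diff(target_times))
    y <- gaussian_smooth(y, sigma / dt)
  }
  y
}

# Random circular shift offsets, at least min_shift_samples away from zero
# (in either direction). Drawn without replacement when enough offsets are
# available, so surrogates are distinct.
random_shifts <- function(n, n_shifts, min_shift_samples) {
  lo <- min(min_shift_samples, floor((n - 1) / 2))
  if (lo < 1) lo <- 1
  pool <- seq.int(lo, n - lo)
  sample(pool, n_shifts, replace = n_shifts > length(pool))
}

#' Circular-shift significance test for a correlation
#'
#' Computes the Pearson correlation of `x` and `y` and builds a null
#' distribution by circularly shifting `y` against `x` `n_shifts` times
#' (random offsets of at least `min_shift` seconds), which preserves the
#' autocorrelation of both signals. Significance follows the percentile
#' rule: the observed r is significant when it falls outside the
#' 2.5th-97.5th percentile interval of the null. A two-sided p-value with
#' add-one correction is also reported.
#'
#' @param x,y numeric vectors of equal length (>= 100 samples). NA pairs
#'   (e.g. blink-masked) are dropped for the observed correlation; shifts
#'   act on the full series.
#' @param n_shifts number of circular shifts (default 500).
#' @param min_shift minimum shift in seconds (default 30).
#' @param dt sample interval in seconds (to convert `min_shift` to samples).
#' @param seed integer seed.
#' @param min_samples minimum series length (default 100).
#'
#' @return An object of class `correlation_result`: list with `r`, `p`,
#'   `significant`, `null_band` (2.5/97.5 percentiles), `n_shifts`.
#' @export
shift_test <- function(x, y, n_shifts = 500, min_shift = 30, dt = 0.133,
                       seed = 1L, min_samples = 100) {
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  n <- length(x)
  if (n < min_samples) stop_invalid("need at least ", min_samples, " samples")
  set.seed(as.integer(seed))
  ok <- is.finite(x) & is.finite(y)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0)
    stop_degenerate("zero variance: correlation undefined")
  r_obs <- cor(x[ok], y[ok])

  shifts <- random_shifts(n, n_shifts, round(min_shift / dt))
  null_r <- vapply(shifts, function(s) {
    ys <- y[c((s + 1):n, 1:s)]
    ok2 <- is.finite(x) & is.finite(ys)
    cor(x[ok2], ys[ok2])
  }, numeric(1))

  band <- unname(quantile(null_r, c(0.025, 0.975)))
  p <- (1 + sum(abs(null_r) >= abs(r_obs))) / (n_shifts + 1)
  structure(list(r = r_obs, p = p,
                 significant = (r_obs < band[1] | r_obs > band[2]),
                 null_band = band, n_shifts = n_shifts,
                 null_r = null_r, seed = as.integer(seed)),
            class = "correlation_result")
}

# Shared preprocessing for cross-correlograms: drift subtraction (8th
# percentile, 180-s window), Gaussian smoothing (sigma 1 s), z-scoring.
preprocess_state_signal <- function(x, dt, drift_window = 180, sigma = 1) {
  x <- x - percentile_baseline(x, dt = dt, window = drift_window, pct = 8)
  x <- gaussian_smooth(x, sigma / dt)
  s <- sd(x)
  if (s == 0) stop_degenerate("zero variance after preprocessing")
  (x - mean(x)) / s
}

#' Cross-correlogram between firing rate and running speed with a null band
#'
#' Both signals (binned on a common grid, conventionally 133 ms) are
#' drift-subtracted (8th percentile in a 180-s moving window), smoothed with
#' a 1-s Gaussian and z-scored; the cross-correlogram is evaluated over
#' lags within `max_lag`. When the data consist of several separate
#' segments, correlograms are computed per segment and averaged; the null
#' band comes from circular shifts of the concatenated speed signal.
#' Positive lags mean the rate lags (follows) the speed.
#'
#' @param rate firing-rate trace, or list of segment traces.
#' @param speed running-speed trace matching `rate` (vector or list).
#' @param dt sample interval in seconds.
#' @param max_lag maximum lag in seconds.
#' @param n_shifts circular shifts for the null band.
#' @param seed integer seed.
#'
#' @return List with `lags` (s), `ccg`, `null_low`, `null_high` (per-lag
#'   2.5/97.5 percentiles of the shift null).
#' @export
cross_correlogram <- function(rate, speed, dt = 0.133, max_lag = 10,
                              n_shifts = 500, seed = 1L) {
  if (!is.list(rate)) rate <- list(rate)
  if (!is.list(speed)) speed <- list(speed)
  stopifnot(length(rate) == length(speed))
  max_lag_n <- round(max_lag / dt)
  if (any(vapply(rate, length, 1L) < 2 * max_lag_n))
    stop_invalid("segment shorter than twice the maximum lag")
  set.seed(as.integer(seed))

  rz <- mapply(preprocess_state_signal, rate, MoreArgs = list(dt = dt),
               SIMPLIFY = FALSE)
  sz <- mapply(preprocess_state_signal, speed, MoreArgs = list(dt = dt),
               SIMPLIFY = FALSE)

  lags <- seq(-max_lag_n, max_lag_n)
  ccg_of <- function(rlist, slist) {
    per_seg <- vapply(seq_along(rlist), function(g) {
      r <- rlist[[g]]; s <- slist[[g]]; n <- length(r)
      vapply(lags, function(l) {
        if (l >= 0) cor(s[1:(n - l)], r[(1 + l):n])
        else cor(s[(1 - l):n], r[1:(n + l)])
      }, numeric(1))
    }, numeric(length(lags)))
    rowMeans(per_seg)
  }
  ccg <- ccg_of(rz, sz)

  # Null: circular shifts of the concatenated speed, re-split into segments.
  scat <- unlist(sz)
  lens <- vapply(sz, length, 1L)
  ends <- cumsum(lens)
  starts <- c(1, head(ends, -1) + 1)
  ntot <- length(scat)
  shifts <- random_shifts(ntot, n_shifts, round(30 / dt))
  null_mat <- vapply(shifts, function(sh) {
    sc <- scat[c((sh + 1):ntot, 1:sh)]
    ccg_of(rz, lapply(seq_along(lens), function(g) sc[starts[g]:ends[g]]))
  }, numeric(length(lags)))
  structure(list(lags = lags * dt, ccg = ccg,
                 null_low = apply(null_mat, 1, quantile, 0.025),
                 null_high = apply(null_mat, 1, quantile, 0.975)),
            class = "cross_correlogram")
}

#' Fisher's combined probability test
#'
#' Combines independent p-values into \eqn{\chi^2 = -2 \sum_c \ln p_c} with
#' \eqn{2n} degrees of freedom and returns the upper-tail probability; used
#' to ask whether the number of units individually correlated with a
#' behavioral variable exceeds independent chance.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#'
#' @return List with `chisq`, `df`, `p`.
#' @export
fisher_combined <- function(p_values) {
  if (length(p_values) == 0) stop_invalid("no p-values supplied")
  if (any(p_values <= 0 | p_values > 1))
    stop_invalid("all p-values must be in (0, 1]")
  chisq <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE))
}

#' Generic permutation test
#'
#' Builds surrogate datasets by permuting `labels` across sample points,
#' recomputes `statistic(values, labels)` for each surrogate, and compares
#' the observed statistic with the null distribution. P-values use the
#' add-one correction so p is never exactly zero.
#'
#' @param values data vector (or anything the statistic accepts; permuted
#'   labels are passed as the second argument).
#' @param labels label vector permuted across sample points.
#' @param statistic function(values, labels) returning a scalar.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param sidedness "two.sided", "greater" or "less".
#'
#' @return An object of class `permutation_result`: list with `observed`,
#'   `p`, `n_perm`, `null`, `seed`.
#' @export
permutation_test <- function(values, labels, statistic, n_perm = 1000,
                             seed = 1L, sidedness = "two.sided") {
  if (n_perm < 100) stop_invalid("n_perm must be >= 100")
  if (length(unique(labels)) < 2) stop_invalid("labels must vary")
  set.seed(as.integer(seed))
  obs <- statistic(values, labels)
  null <- vapply(seq_len(n_perm),
                 function(i) statistic(values, sample(labels)), numeric(1))
  p <- switch(sidedness,
    greater = (1 + sum(null >= obs)) / (n_perm + 1),
    less = (1 + sum(null <= obs)) / (n_perm + 1),
    two.sided = (1 + sum(abs(null - mean(null)) >= abs(obs - mean(null)))) /
      (n_perm + 1),
    stop_invalid("unknown sidedness"))
  structure(list(observed = obs, p = p, n_perm = n_perm, null = null,
                 seed = as.integer(seed)),
            class = "permutation_result")
}

# Wrap an angular difference into (-period/2, period/2].
wrap_angle <- function(x, period = 360) {
  w <- x %% period
  w[w > period / 2] <- w[w > period / 2] - period
  w
}

# Confidence half-width (radians) of the circular mean direction at level
# alpha, after Zar (Biostatistical Analysis, eqs. 26.24-26.25).
circ_mean_conf <- function(alpha_rad, alpha_level = 0.05) {
  n <- length(alpha_rad)
  C <- sum(cos(alpha_rad)); S <- sum(sin(alpha_rad))
  R <- sqrt(C^2 + S^2)
  rbar <- R / n
  chi <- qchisq(1 - alpha_level, df = 1)
  if (rbar < sqrt(chi / (2 * n))) return(list(t = pi, mean = atan2(S, C)))
  arg <- if (rbar <= 0.9) {
    sqrt((2 * n * (2 * R^2 - n * chi)) / (4 * n - chi)) / R
  } else {
    sqrt(n^2 - (n^2 - R^2) * exp(chi / n)) / R
  }
  arg <- min(1, max(-1, arg))
  list(t = acos(arg), mean = atan2(S, C))
}

#' Circular paired test of mean direction
#'
#' Tests whether paired angular measurements differ on average: computes the
#' circular differences `angles_a - angles_b` on the given period, then asks
#' whether the confidence interval of their circular mean excludes zero
#' (the circular analogue of a paired t-test, as in the CircStat toolbox's
#' `circ_mtest`). An approximate p-value is obtained by bisection on the
#' confidence level at which zero leaves the interval.
#'
#' @param angles_a,angles_b paired angles in degrees (length >= 5).
#' @param period 360 for directions, 180 for orientations.
#'
#' @return List with `reject` (at the 0.05 level), `p` (approximate),
#'   `mean_diff` (degrees, wrapped), `n`.
#' @export
circular_paired_test <- function(angles_a, angles_b, period = 360) {
  if (length(angles_a) != length(angles_b))
    stop_invalid("paired samples must have equal length")
  if (length(angles_a) < 5) stop_invalid("need at least 5 pairs")
  if (!period %in% c(180, 360)) stop_invalid("period must be 180 or 360")
  d <- wrap_angle(angles_a - angles_b, period)
  rad <- d * 2 * pi / period  # map one period onto the full circle

  inside <- function(alpha_level) {
    ci <- circ_mean_conf(rad, alpha_level)
    abs(wrap_angle(ci$mean * 180 / pi, 360)) * pi / 180 <= ci$t
  }
  reject <- !inside(0.05)
  # Bisection: smallest alpha at which zero is excluded (p approximate).
  lo <- 1e-6; hi <- 1 - 1e-6
  if (!inside(lo)) p <- lo
  else if (inside(hi)) p <- 1
  else {
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (inside(mid)) lo <- mid else hi <- mid
    }
    p <- hi
  }
  mean_rad <- atan2(sum(sin(rad)), sum(cos(rad)))
  list(reject = reject, p = p,
       mean_diff = wrap_angle(mean_rad * period / (2 * pi), period),
       n = length(d))
}
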