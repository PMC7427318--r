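# Direction-tuning analysis: wrapped double-Gaussian curves, single and
# state-constrained fits, tuned-vs-flat cross-validation, vector-sum
# selectivity indices, arousal modulation indices and their permutation
# tests, and harmonic summaries of preferred-direction distributions.

#' Construct a direction-tuning parameter set
#'
#' The tuning curve is a sum of two wrapped Gaussians with peaks 180
#' degrees apart plus an additive offset, parameterized by preferred
#' direction `theta_p`, response at the preferred direction above offset
#' `P`, width `sigma`, direction selectivity `DS = (P - N)/(P + N)` (the
#' null-direction response `N = P (1 - DS)/(1 + DS)` is derived, never
#' stored) and `offset`.
#'
#' @param theta_p preferred direction in degrees.
#' @param P peak response above offset.
#' @param sigma wrapped-Gaussian sigma in degrees (> 0).
#' @param DS direction selectivity in \[0, 1\].
#' @param offset additive baseline.
#'
#' @return An object of class `tuning_params`.
#' @export
tuning_params <- function(theta_p, P, sigma, DS, offset) {
  if (sigma <= 0) stop_invalid("sigma must be > 0")
  if (DS < 0 || DS > 1) stop_invalid("DS must be in [0, 1]")
  structure(list(theta_p = theta_p %% 360, P = P, sigma = sigma, DS = DS,
                 offset = offset),
            class = "tuning_params")
}

# Wrapped Gaussian normalized to 1 at x = 0; wrap terms k in -2..2.
wrapped_gauss_norm <- function(x, sigma) {
  num <- 0; den <- 0
  for (k in -2:2) {
    num <- num + exp(-(x + 360 * k)^2 / (2 * sigma^2))
    den <- den + exp(-(360 * k)^2 / (2 * sigma^2))
  }
  num / den
}

# Unit-peak tuning shape: h(theta_p) = 1, h(theta_p + 180) = (1-DS)/(1+DS).
tuning_shape <- function(theta, theta_p, sigma, DS) {
  g1 <- wrapped_gauss_norm(wrap_angle(theta - theta_p), sigma)
  g2 <- wrapped_gauss_norm(wrap_angle(theta - theta_p - 180), sigma)
  u <- wrapped_gauss_norm(180, sigma)
  nn <- (1 - DS) / (1 + DS)
  denom <- 1 - u^2
  if (abs(denom) < 1e-12) return((g1 + g2) / (1 + u))
  a <- (1 - nn * u) / denom
  b <- (nn - u) / denom
  a * g1 + b * g2
}

#' Evaluate the wrapped double-Gaussian tuning curve
#'
#' \eqn{f(\theta) = offset + a\,\tilde w(\theta - \theta_p; \sigma) +
#' b\,\tilde w(\theta - \theta_p - 180; \sigma)}, where \eqn{\tilde w} is
#' the wrapped Gaussian normalized to 1 at its peak and (a, b) are chosen
#' so that `f(theta_p) = offset + P` and `f(theta_p + 180) = offset + N`
#' hold exactly.
#'
#' @param theta stimulus directions in degrees (vectorized).
#' @param params a [tuning_params()] object.
#'
#' @return Numeric response values.
#' @export
wrapped_double_gaussian <- function(theta, params) {
  if (params$sigma <= 0) stop_invalid("sigma must be > 0")
  params$offset + params$P *
    tuning_shape(theta, params$theta_p, params$sigma, params$DS)
}

# Profiled least squares: given the nonlinear shape parameters, solve the
# per-state linear parameters (offset, P >= 0) and return SSE + coefs.
profile_state_fit <- function(y, h) {
  X <- cbind(1, h)
  fit <- lm.fit(X, y)
  P <- unname(fit$coefficients[2])
  if (is.na(P) || P < 0) {
    off <- mean(y)
    return(list(offset = off, P = 0, sse = sum((y - off)^2)))
  }
  list(offset = unname(fit$coefficients[1]), P = P,
       sse = sum(fit$residuals^2))
}

# Vector-sum initial guesses for theta_p and a moment-based sigma.
tuning_inits <- function(amplitudes, directions, spacing) {
  amp <- pmax(amplitudes - min(amplitudes), 0)
  if (sum(amp) == 0) amp <- rep(1, length(amplitudes))
  z <- sum(amp * exp(1i * directions * pi / 180)) / sum(amp)
  theta0 <- (Arg(z) * 180 / pi) %% 360
  # circular SD of the direction distribution weighted by amplitude
  r <- Mod(z)
  sig0 <- if (r > 0 && r < 1) sqrt(-2 * log(r)) * 180 / pi / 2 else 35
  sig0 <- min(90, max(spacing, sig0))
  list(theta0 = theta0, sigma0 = sig0)
}

#' Fit a wrapped double-Gaussian tuning curve to trial responses
#'
#' Bounded nonlinear least squares with the linear parameters (offset, P)
#' profiled out: the optimizer searches (theta_p, sigma, DS) with sigma
#' bounded below by the direction sampling interval and DS in \[0, 1\],
#' multi-starting from four initial preferred directions (the vector-sum
#' estimate plus 90/180/270-degree rotations); ties are broken toward
#' smaller sigma. Responses of units suppressed by gratings are negated
#' before fitting (for those units the preferred direction elicits the
#' largest activity drop).
#'
#' @param amplitudes per-trial response amplitudes.
#' @param directions per-trial stimulus directions in degrees.
#' @param suppressed logical; negate amplitudes before fitting.
#' @param direction_spacing sampling interval between tested directions in
#'   degrees (lower bound for sigma); default inferred from `directions`.
#'
#' @return A [tuning_params()] object with additional fields `sse`,
#'   `flat` (TRUE when the fit degenerated to a constant).
#' @export
fit_tuning <- function(amplitudes, directions, suppressed = FALSE,
                       direction_spacing = NULL) {
  stopifnot(length(amplitudes) == length(directions))
  y <- if (suppressed) -amplitudes else amplitudes
  dirs_u <- sort(unique(directions %% 360))
  if (is.null(direction_spacing))
    direction_spacing <- min(diff(c(dirs_u, dirs_u[1] + 360)))
  if (sd(y) == 0) {
    warning("all amplitudes identical; returning flat fit")
    out <- tuning_params(0, 0, direction_spacing, 0, y[1])
    out$sse <- 0; out$flat <- TRUE
    return(out)
  }
  ini <- tuning_inits(y, directions, direction_spacing)

  obj <- function(par) {
    h <- tuning_shape(directions, par[1], par[2], par[3])
    profile_state_fit(y, h)$sse
  }
  best <- NULL
  for (dth in c(0, 90, 180, 270)) {
    start <- c(ini$theta0 + dth, ini$sigma0, 0.5)
    fit <- optim(start, obj, method = "L-BFGS-B",
                 lower = c(-Inf, direction_spacing, 0),
                 upper = c(Inf, 200, 1),
                 control = list(maxit = 400, factr = 1e2,
                                ndeps = c(1e-5, 1e-5, 1e-5)))
    if (is.null(best) || fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 && fit$par[2] < best$par[2]))
      best <- fit
  }
  h <- tuning_shape(directions, best$par[1], best$par[2], best$par[3])
  lin <- profile_state_fit(y, h)
  out <- tuning_params(best$par[1], lin$P, best$par[2], best$par[3],
                       lin$offset)
  out$sse <- lin$sse
  out$flat <- lin$P == 0
  out
}

#' Jointly fit tuning curves across behavioral (and optogenetic) states
#'
#' For a pupil pair (`share = "shape"`), the two curves are constrained to
#' have equal preferred direction, tuning width and direction selectivity;
#' only the amplitude `P` and `offset` vary per state. For the pupil-by-
#' laser quadruple (`share = "theta"`), only the preferred direction is
#' shared; each condition keeps its own sigma, DS, P and offset. A single
#' pooled fit over all trials provides the initial parameters.
#'
#' @param amplitudes per-trial response amplitudes.
#' @param directions per-trial directions in degrees.
#' @param state_labels character/factor state per trial (2 or more states).
#' @param share "shape" (theta_p, sigma, DS shared) or "theta" (theta_p
#'   only).
#' @param suppressed logical; negate amplitudes before fitting.
#' @param n_starts number of theta_p multi-starts (1 skips the rotated
#'   restarts; used inside permutation loops).
#'
#' @return An object of class `arousal_tuning_pair`: list with `shared`
#'   (theta_p, and sigma/DS when shared), `states` (named list with P,
#'   offset, and per-condition sigma/DS when not shared), `sse`,
#'   `response_modulation` and `depth_modulation` (large vs small pupil,
#'   when states are named "small"/"large").
#' @export
fit_tuning_by_state <- function(amplitudes, directions, state_labels,
                                share = c("shape", "theta"),
                                suppressed = FALSE, n_starts = 4) {
  share <- match.arg(share)
  stopifnot(length(amplitudes) == length(directions),
            length(amplitudes) == length(state_labels))
  states <- unique(as.character(state_labels))
  counts <- table(state_labels)
  if (any(counts == 0) || length(states) < 2)
    stop_invalid("every state must contain trials")
  y <- if (suppressed) -amplitudes else amplitudes
  lab <- as.character(state_labels)
  dirs_u <- sort(unique(directions %% 360))
  spacing <- min(diff(c(dirs_u, dirs_u[1] + 360)))

  pooled <- fit_tuning(y, directions, suppressed = FALSE,
                       direction_spacing = spacing)
  idx <- lapply(states, function(s) which(lab == s))
  names(idx) <- states

  if (share == "shape") {
    obj <- function(par) {
      sse <- 0
      for (s in states) {
        h <- tuning_shape(directions[idx[[s]]], par[1], par[2], par[3])
        sse <- sse + profile_state_fit(y[idx[[s]]], h)$sse
      }
      sse
    }
    starts <- if (n_starts > 1) c(0, 90, 180, 270)[seq_len(n_starts)] else 0
    best <- NULL
    for (dth in starts) {
      fit <- optim(c(pooled$theta_p + dth, pooled$sigma, pooled$DS), obj,
                   method = "L-BFGS-B",
                   lower = c(-Inf, spacing, 0), upper = c(Inf, 200, 1),
                   control = list(maxit = 400, factr = 1e2,
                                  ndeps = rep(1e-5, 3)))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    shared <- list(theta_p = best$par[1] %% 360, sigma = best$par[2],
                   DS = best$par[3])
    per_state <- lapply(states, function(s) {
      h <- tuning_shape(directions[idx[[s]]], best$par[1], best$par[2],
                        best$par[3])
      lin <- profile_state_fit(y[idx[[s]]], h)
      list(P = lin$P, offset = lin$offset, sigma = best$par[2],
           DS = best$par[3])
    })
    sse <- best$value
  } else {
    ns <- length(states)
    # par = theta_p, then (sigma, DS) per condition
    obj <- function(par) {
      sse <- 0
      for (k in seq_len(ns)) {
        h <- tuning_shape(directions[idx[[k]]], par[1], par[2 * k],
                          par[2 * k + 1])
        sse <- sse + profile_state_fit(y[idx[[k]]], h)$sse
      }
      sse
    }
    start <- c(pooled$theta_p, rep(c(pooled$sigma, pooled$DS), ns))
    starts <- if (n_starts > 1) c(0, 90, 180, 270)[seq_len(n_starts)] else 0
    best <- NULL
    for (dth in starts) {
      st <- start; st[1] <- st[1] + dth
      fit <- optim(st, obj, method = "L-BFGS-B",
                   lower = c(-Inf, rep(c(spacing, 0), ns)),
                   upper = c(Inf, rep(c(200, 1), ns)),
                   control = list(maxit = 600, factr = 1e2,
                                  ndeps = rep(1e-5, 1 + 2 * ns)))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    shared <- list(theta_p = best$par[1] %% 360)
    per_state <- lapply(seq_len(ns), function(k) {
      h <- tuning_shape(directions[idx[[k]]], best$par[1], best$par[2 * k],
                        best$par[2 * k + 1])
      lin <- profile_state_fit(y[idx[[k]]], h)
      list(P = lin$P, offset = lin$offset, sigma = best$par[2 * k],
           DS = best$par[2 * k + 1])
    })
    sse <- best$value
  }
  names(per_state) <- states

  out <- structure(list(shared = shared, states = per_state, sse = sse,
                        share = share, suppressed = suppressed),
                   class = "arousal_tuning_pair")
  if (all(c("small", "large") %in% states)) {
    L <- per_state$large$offset + per_state$large$P
    S <- per_state$small$offset + per_state$small$P
    out$response_modulation <- if (L + S != 0) modulation_index(L, S) else NA
    grid <- seq(0, 359, by = 1)
    depth <- vapply(c("small", "large"), function(s) {
      p <- per_state[[s]]
      f <- p$offset + p$P * tuning_shape(grid, shared$theta_p, p$sigma, p$DS)
      max(f) - min(f)
    }, numeric(1))
    out$depth_modulation <- if (sum(depth) != 0)
      unname(modulation_index(depth[["large"]], depth[["small"]])) else NA
  }
  out
}

#' Cross-validated tuned-versus-flat classification
#'
#' Leave-one-repeat-out cross-validation: for each fold, one trial per
#' direction is held out, the wrapped double Gaussian and a constant are
#' fitted to the remaining trials, and both models are scored by explained
#' variance on the held-out trials. A unit is tuned when the mean held-out
#' explained variance of the Gaussian exceeds that of the constant. For
#' untuned units the response at the preferred direction is defined as the
#' constant fitted to all stimuli.
#'
#' @param amplitudes per-trial response amplitudes.
#' @param directions per-trial directions in degrees.
#' @param suppressed logical; negate before fitting.
#'
#' @return List with `is_tuned`, `cv_ev_gauss`, `cv_ev_const`.
#' @export
classify_tuned <- function(amplitudes, directions, suppressed = FALSE) {
  y <- if (suppressed) -amplitudes else amplitudes
  dirs <- directions %% 360
  by_dir <- split(seq_along(y), dirs)
  n_rep <- min(lengths(by_dir))
  if (n_rep < 3) stop_invalid("need at least 3 repeats per direction")
  ev <- function(obs, pred) {
    sst <- sum((obs - mean(obs))^2)
    if (sst == 0) return(0)
    1 - sum((obs - pred)^2) / sst
  }
  ev_g <- ev_c <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    held <- vapply(by_dir, `[`, integer(1), r)
    train <- setdiff(seq_along(y), held)
    fit <- fit_tuning(y[train], dirs[train])
    pred_g <- wrapped_double_gaussian(dirs[held], fit)
    pred_c <- rep(mean(y[train]), length(held))
    ev_g[r] <- ev(y[held], pred_g)
    ev_c[r] <- ev(y[held], pred_c)
  }
  list(is_tuned = mean(ev_g) > mean(ev_c),
       cv_ev_gauss = mean(ev_g), cv_ev_const = mean(ev_c))
}

#' Vector-sum direction and orientation selectivity
#'
#' Mean response amplitudes scale unit vectors pointing into the stimulus
#' directions; the normalized resultant
#' \eqn{R = \sum_k R_k e^{i\alpha_k} / \sum_k R_k} gives the preferred
#' direction (angle) and DSI (length). For orientation selectivity the
#' angles are doubled first and the preferred orientation is reported
#' modulo 180 degrees. Amplitudes of suppressed units are inverted, and
#' remaining negative amplitudes are set to zero.
#'
#' @param mean_amplitudes mean response per direction.
#' @param directions stimulus directions in degrees (distinct).
#' @param suppressed logical; invert amplitudes first.
#'
#' @return An object of class `selectivity_result`: list with
#'   `pref_direction`, `dsi`, `pref_orientation`, `osi`.
#' @export
vector_selectivity <- function(mean_amplitudes, directions,
                               suppressed = FALSE) {
  if (anyDuplicated(directions %% 360)) stop_invalid("directions must be distinct")
  amp <- if (suppressed) -mean_amplitudes else mean_amplitudes
  amp <- pmax(amp, 0)
  if (sum(amp) == 0)
    stop_degenerate("all amplitudes zero after clipping; selectivity undefined")
  a <- directions * pi / 180
  Rd <- sum(amp * exp(1i * a)) / sum(amp)
  Ro <- sum(amp * exp(2i * a)) / sum(amp)
  structure(list(pref_direction = (Arg(Rd) * 180 / pi) %% 360,
                 dsi = Mod(Rd),
                 pref_orientation = (Arg(Ro) * 180 / pi / 2) %% 180,
                 osi = Mod(Ro)),
            class = "selectivity_result")
}

#' Permutation significance of direction (or orientation) selectivity
#'
#' Stimulus directions are permuted across trials (default 1,000 times);
#' the one-sided p-value is the add-one-corrected fraction of permutations
#' whose selectivity index reaches the observed one.
#'
#' @param amplitudes per-trial response amplitudes.
#' @param directions per-trial directions in degrees.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param measure "dsi" or "osi".
#' @param suppressed logical; invert amplitudes first.
#'
#' @return List with `observed`, `p`.
#' @export
selectivity_significance <- function(amplitudes, directions, n_perm = 1000,
                                     seed = 1L, measure = c("dsi", "osi"),
                                     suppressed = FALSE) {
  measure <- match.arg(measure)
  if (n_perm < 100) stop_invalid("n_perm must be >= 100")
  set.seed(as.integer(seed))
  amp <- if (suppressed) -amplitudes else amplitudes
  stat <- function(dirs) {
    m <- tapply(amp, dirs %% 360, mean)
    v <- try(vector_selectivity(as.numeric(m), as.numeric(names(m))),
             silent = TRUE)
    if (inherits(v, "try-error")) return(0)
    v[[measure]]
  }
  obs <- stat(directions)
  null <- vapply(seq_len(n_perm), function(i) stat(sample(directions)),
                 numeric(1))
  list(observed = obs, p = (1 + sum(null >= obs)) / (n_perm + 1))
}

#' Arousal modulation index
#'
#' \eqn{M = (L - S) / \left[\tfrac{1}{2}(L + S)\right]}, comparing a
#' quantity in large-pupil versus small-pupil trials; applied to responses
#' at the preferred direction (response modulation) and to tuning depth
#' (depth modulation, tuned units only). Ranges over \[-2, 2\].
#'
#' @param L value in the large-pupil state.
#' @param S value in the small-pupil state.
#'
#' @return Dimensionless modulation index.
#' @export
modulation_index <- function(L, S) {
  if (L + S == 0) stop_degenerate("L + S = 0: modulation index undefined")
  (L - S) / (0.5 * (L + S))
}

#' Permutation significance of arousal modulation
#'
#' Permutes the small/large-pupil trial labels (default 200 times), refits
#' the constrained tuning pair for each permutation, and compares the
#' observed modulation index with the null distribution (two-sided,
#' add-one corrected). With `share = "theta"` the same engine serves the
#' control-versus-inactivation contrast.
#'
#' @param amplitudes per-trial response amplitudes.
#' @param directions per-trial directions in degrees.
#' @param state_labels per-trial state ("small"/"large").
#' @param n_perm number of permutations (>= 20).
#' @param seed integer seed.
#' @param measure "response" or "depth".
#' @param share parameter-sharing mode, see [fit_tuning_by_state()].
#'
#' @return List with `observed`, `p`, `n_perm`.
#' @export
modulation_significance <- function(amplitudes, directions, state_labels,
                                    n_perm = 200, seed = 1L,
                                    measure = c("response", "depth"),
                                    share = "shape") {
  measure <- match.arg(measure)
  if (n_perm < 20) stop_invalid("n_perm must be >= 20")
  if (length(unique(state_labels)) < 2)
    stop_invalid("both states must be populated")
  set.seed(as.integer(seed))
  field <- paste0(measure, "_modulation")
  mi <- function(labels, n_starts) {
    fit <- fit_tuning_by_state(amplitudes, directions, labels, share = share,
                               n_starts = n_starts)
    v <- fit[[field]]
    if (is.null(v) || is.na(v)) 0 else v
  }
  obs <- mi(state_labels, 4)
  null <- vapply(seq_len(n_perm), function(i) mi(sample(state_labels), 1),
                 numeric(1))
  list(observed = obs, p = (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1),
       n_perm = n_perm)
}

#' Harmonic summary of a preferred-direction distribution
#'
#' Magnitude and phase of the `harmonic`-th circular moment
#' \eqn{m_h = \mathrm{mean}(e^{i h \theta})} of a set of preferred
#' directions; the fourth harmonic captures clustering at the four cardinal
#' axes.
#'
#' @param preferred_directions angles in degrees (>= 8 values).
#' @param harmonic harmonic order (default 4).
#'
#' @return List with `amplitude` (in \[0, 1\]) and `phase` (degrees in the
#'   harmonic domain; divide by `harmonic` for the axis location).
#' @export
direction_histogram_harmonic <- function(preferred_directions, harmonic = 4) {
  if (length(preferred_directions) < 8) stop_invalid("need at least 8 values")
  m <- mean(exp(1i * harmonic * preferred_directions * pi / 180))
  list(amplitude = Mod(m), phase = (Arg(m) * 180 / pi) %% 360)
}
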