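test_that("wrapped double Gaussian enforces its peak and null values", {
  p <- tuning_params(90, 2, 35, 0.8, 0.5)
  expect_equal(wrapped_double_gaussian(90, p), 2.5, tolerance = 1e-12)
  N <- 2 * (1 - 0.8) / (1 + 0.8)
  expect_equal(wrapped_double_gaussian(270, p), 0.5 + N, tolerance = 1e-12)
  p1 <- tuning_params(10, 3, 40, 1, 1)
  expect_equal(wrapped_double_gaussian(190, p1), 1, tolerance = 1e-12)
  expect_error(wrapped_double_gaussian(0, list(sigma = -1)),
               class = "retistate_invalid")
  expect_error(tuning_params(0, 1, 30, 1.2, 0), class = "retistate_invalid")
})

test_that("tuning fits recover exact curves and handle flat data", {
  dirs <- rep(seq(0, 330, by = 30), 5)
  y <- tuning_amplitudes(90, 35, 0.8, 2, 0.5, dirs)
  fit <- fit_tuning(y, dirs)
  expect_equal(fit$theta_p, 90, tolerance = 1e-6)
  expect_equal(fit$sigma, 35, tolerance = 1e-5)
  expect_equal(fit$DS, 0.8, tolerance = 1e-6)
  expect_equal(fit$P, 2, tolerance = 1e-6)
  expect_equal(fit$offset, 0.5, tolerance = 1e-6)

  expect_warning(flat <- fit_tuning(rep(1.3, length(dirs)), dirs))
  expect_equal(flat$P, 0)
  expect_equal(flat$offset, 1.3)

  # suppressed units are fitted on negated responses
  ysup <- -y
  fs <- fit_tuning(ysup, dirs, suppressed = TRUE)
  expect_equal(fs$theta_p, 90, tolerance = 1e-6)
})

test_that("noisy tuning fits recover preferred direction and DS", {
  set.seed(21)
  errs <- t(vapply(1:25, function(i) {
    th <- runif(1, 0, 360); ds <- runif(1, 0.3, 1)
    y <- tuning_amplitudes(th, 40, ds, 2, 0.5,
                           rep(seq(0, 330, by = 30), 15), noise_sd = 0.4)
    f <- fit_tuning(y, rep(seq(0, 330, by = 30), 15))
    c(abs(retistate:::wrap_angle(f$theta_p - th)), abs(f$DS - ds))
  }, numeric(2)))
  expect_lt(median(errs[, 1]), 5)
  expect_lt(median(errs[, 2]), 0.1)
})

test_that("state-constrained pair shares shape and recovers the gain ratio", {
  set.seed(22)
  dirs <- rep(seq(0, 330, by = 30), 10)
  states <- rep(c("small", "large"), length.out = length(dirs))
  ratios <- vapply(1:15, function(i) {
    th <- runif(1, 0, 360)
    y <- ifelse(states == "small",
                tuning_amplitudes(th, 35, 0.7, 1, 0.1, dirs),
                tuning_amplitudes(th, 35, 0.7, 0.7, 0.1, dirs)) +
      rnorm(length(dirs), 0, 0.2)
    fit <- fit_tuning_by_state(y, dirs, states)
    (fit$states$large$offset + fit$states$large$P) /
      (fit$states$small$offset + fit$states$small$P)
  }, numeric(1))
  expect_gt(median(ratios), 0.6)
  expect_lt(median(ratios), 0.8)

  expect_error(fit_tuning_by_state(dirs * 0, dirs, rep("small", length(dirs))),
               class = "retistate_invalid")
})

test_that("identical generative parameters give centered modulation", {
  set.seed(23)
  dirs <- rep(seq(0, 330, by = 30), 10)
  states <- rep(c("small", "large"), length.out = length(dirs))
  mods <- vapply(1:15, function(i) {
    y <- tuning_amplitudes(120, 35, 0.8, 1.5, 0.2, dirs, noise_sd = 0.2)
    fit_tuning_by_state(y, dirs, states)$response_modulation
  }, numeric(1))
  expect_lt(abs(median(mods)), 0.05)
})

test_that("pair fit with a single effective state matches the single fit", {
  dirs <- rep(seq(0, 330, by = 30), 6)
  y <- tuning_amplitudes(200, 45, 0.6, 2, 0.3, dirs, noise_sd = 0.15,
                         seed = 24)
  # two identical halves labeled as different states
  states <- rep(c("small", "large"), length.out = length(dirs))
  single <- fit_tuning(y, dirs)
  pair <- fit_tuning_by_state(y, dirs, states)
  expect_equal(pair$shared$theta_p, single$theta_p, tolerance = 0.5)
  expect_equal(pair$shared$sigma, single$sigma, tolerance = 0.5)
  expect_equal(pair$shared$DS, single$DS, tolerance = 0.02)
})

test_that("quadruple fit ties only the preferred direction", {
  set.seed(25)
  dirs <- rep(seq(0, 330, by = 30), 12)
  cond <- rep(c("ctrl_small", "ctrl_large", "inact_small", "inact_large"),
              length.out = length(dirs))
  sig <- c(ctrl_small = 30, ctrl_large = 30, inact_small = 55,
           inact_large = 55)
  amp <- c(ctrl_small = 2, ctrl_large = 1.4, inact_small = 1,
           inact_large = 1)
  y <- vapply(seq_along(dirs), function(i) {
    tuning_amplitudes(90, sig[cond[i]], 0.8, amp[cond[i]], 0.2, dirs[i])
  }, numeric(1)) + rnorm(length(dirs), 0, 0.1)
  fit <- fit_tuning_by_state(y, dirs, cond, share = "theta")
  expect_equal(fit$shared$theta_p, 90, tolerance = 3)
  expect_lt(fit$states$ctrl_small$sigma, 40)
  expect_gt(fit$states$inact_small$sigma, 42)
})

test_that("cross-validated model comparison separates tuned from flat", {
  set.seed(26)
  dirs <- rep(seq(0, 330, by = 30), 5)
  tuned_hits <- vapply(1:10, function(i) {
    y <- tuning_amplitudes(45, 35, 0.9, 2, 0.3, dirs, noise_sd = 0.4)
    classify_tuned(y, dirs)$is_tuned
  }, logical(1))
  expect_gte(mean(tuned_hits), 0.9)

  flat_hits <- vapply(1:10, function(i) {
    classify_tuned(rnorm(length(dirs), 1, 0.3), dirs)$is_tuned
  }, logical(1))
  expect_lte(mean(flat_hits), 0.5)

  expect_false(suppressWarnings(classify_tuned(rep(1, length(dirs)),
                                               dirs)$is_tuned))
  expect_error(classify_tuned(rnorm(24), rep(seq(0, 330, by = 30), 2)),
               class = "retistate_invalid")
})

test_that("vector selectivity matches hand calculations and the oracle", {
  expect_equal(vector_selectivity(c(1, 1, 1, 1), c(0, 90, 180, 270))$dsi, 0,
               tolerance = 1e-12)
  v <- vector_selectivity(c(1, 0, 0, 0), c(0, 90, 180, 270))
  expect_equal(v$dsi, 1, tolerance = 1e-12)
  expect_equal(v$pref_direction, 0, tolerance = 1e-12)
  v2 <- vector_selectivity(c(2, 1, 0, 1), c(0, 90, 180, 270))
  expect_equal(v2$dsi, 0.5, tolerance = 1e-12)
  expect_equal(v2$pref_direction, 0, tolerance = 1e-9)
  # both axes carry equal summed response here, so OSI vanishes
  expect_equal(v2$osi, 0, tolerance = 1e-12)

  # brute-force complex-sum oracle on random inputs
  set.seed(27)
  for (i in 1:20) {
    amp <- runif(8); dirs <- seq(0, 315, by = 45)
    v <- vector_selectivity(amp, dirs)
    z <- sum(amp * exp(1i * dirs * pi / 180)) / sum(amp)
    zo <- sum(amp * exp(2i * dirs * pi / 180)) / sum(amp)
    expect_equal(v$dsi, Mod(z), tolerance = 1e-12)
    expect_equal(v$osi, Mod(zo), tolerance = 1e-12)
  }
  expect_error(vector_selectivity(c(-1, -2), c(0, 90)),
               class = "retistate_degenerate")
})

test_that("selectivity is rotation-equivariant", {
  set.seed(28)
  amp <- runif(12, 0, 2)
  dirs <- seq(0, 330, by = 30)
  v0 <- vector_selectivity(amp, dirs)
  for (delta in c(10, 45, 123)) {
    vr <- vector_selectivity(amp, dirs + delta)
    expect_equal(vr$dsi, v0$dsi, tolerance = 1e-12)
    expect_equal(vr$osi, v0$osi, tolerance = 1e-12)
    expect_equal(retistate:::wrap_angle(vr$pref_direction -
                                          v0$pref_direction - delta), 0,
                 tolerance = 1e-9)
  }
})

test_that("selectivity permutation test detects tuning and stays calibrated", {
  set.seed(29)
  dirs <- rep(seq(0, 330, by = 30), 15)
  y <- tuning_amplitudes(0, 35, 0.9, 2, 0.2, dirs, noise_sd = 0.3)
  r <- selectivity_significance(y, dirs, n_perm = 200, seed = 1)
  expect_lt(r$p, 0.05)

  ynull <- sample(y)
  rn <- selectivity_significance(ynull, dirs, n_perm = 200, seed = 2)
  expect_gt(rn$p, 0.001)

  r0 <- selectivity_significance(rep(c(1, 1, 1, 1), 10),
                                 rep(c(0, 90, 180, 270), 10),
                                 n_perm = 100, seed = 3)
  expect_gt(r0$p, 0.9)
})

test_that("modulation index obeys its identities and bounds", {
  expect_equal(modulation_index(1, 1), 0)
  expect_equal(modulation_index(1, 0), 2)
  expect_equal(modulation_index(3, 1), 1)
  expect_error(modulation_index(1, -1), class = "retistate_degenerate")
  set.seed(30)
  for (i in 1:20) {
    L <- runif(1, 0, 5); S <- runif(1, 0.01, 5)
    m <- modulation_index(L, S)
    expect_equal(m, -modulation_index(S, L), tolerance = 1e-12)
    expect_true(m >= -2 && m <= 2)
  }
})

test_that("modulation permutation test has power and honors arguments", {
  set.seed(31)
  dirs <- rep(seq(0, 330, by = 30), 10)
  states <- rep(c("small", "large"), length.out = length(dirs))
  y <- ifelse(states == "small",
              tuning_amplitudes(60, 35, 0.7, 2, 0.1, dirs),
              tuning_amplitudes(60, 35, 0.7, 1, 0.1, dirs)) +
    rnorm(length(dirs), 0, 0.2)
  r <- modulation_significance(y, dirs, states, n_perm = 99, seed = 1)
  expect_lt(r$p, 0.05)
  expect_lt(r$observed, 0)

  expect_error(modulation_significance(y, dirs, states, n_perm = 0),
               class = "retistate_invalid")
  expect_error(modulation_significance(y, dirs, rep("small", length(dirs)),
                                       n_perm = 99),
               class = "retistate_invalid")
})

test_that("fourth-harmonic summary captures cardinal clustering", {
  set.seed(32)
  u <- runif(2000, 0, 360)
  expect_lt(direction_histogram_harmonic(u)$amplitude, 0.05)

  card <- rep(c(0, 90, 180, 270), 50) + rnorm(200, 0, 5)
  h <- direction_histogram_harmonic(card)
  expect_gt(h$amplitude, 0.5)
  expect_lt(min(h$phase, 360 - h$phase), 45)

  expect_equal(direction_histogram_harmonic(rep(33, 10))$amplitude, 1,
               tolerance = 1e-12)
  expect_error(direction_histogram_harmonic(1:5),
               class = "retistate_invalid")
})
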