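test_that("kernel/scaling fit reconstructs a known forward model", {
  qs <- quick_schedule(4, 4, seed = 1)
  set.seed(2)
  gains <- runif(length(qs$schedule$trial_onsets), 0.5, 2)
  y <- forward_trace(qs$schedule, qs$times, gains, tau = 0.5,
                     noise_sd = 0.05, seed = 3)
  fit <- fit_kernel_scaling(y, qs$schedule, qs$times)
  pred <- fit$intercept
  expect_gt(fit$adjusted_r2, 0.8)
  expect_gt(cor(fit$scalings, gains), 0.98)
  # reconstruction of the signal itself
  recon <- forward_trace(qs$schedule, qs$times, fit$scalings * max(fit$kernel),
                         tau = 0.5)
  expect_gt(cor(recon, y), 0.9)
})

test_that("noiseless fits recover the scaling-kernel product exactly", {
  qs <- quick_schedule(4, 2, seed = 4)
  gains <- rep(1.7, length(qs$schedule$trial_onsets))
  y <- forward_trace(qs$schedule, qs$times, gains, tau = 0.4, noise_sd = 0)
  fit <- fit_kernel_scaling(y, qs$schedule, qs$times, tol = 1e-12,
                            max_iter = 200)
  # product s * k equals the true gain * true kernel at the onset sample
  klen <- fit$klen
  dt <- qs$dt
  true_k <- exp(-(seq_len(klen) - 1) * dt / 0.4)
  true_k[true_k < exp(-5)] <- 0  # forward kernel truncated at 5 tau
  prod_fit <- outer(fit$kernel, fit$scalings)
  prod_true <- outer(true_k, gains)
  expect_lt(max(abs(prod_fit - prod_true)), 1e-8)
})

test_that("null signals give near-zero scalings and R-squared", {
  qs <- quick_schedule(4, 4, seed = 5)
  set.seed(6)
  y <- rnorm(length(qs$times), 0, 0.3)
  fit <- fit_kernel_scaling(y, qs$schedule, qs$times)
  expect_lt(mean(abs(fit$scalings)), 0.35)
  expect_lt(fit$adjusted_r2, 0.1)
  expect_error(fit_kernel_scaling(rep(1, length(qs$times)), qs$schedule,
                                  qs$times),
               class = "retistate_degenerate")
})

test_that("training MSE is non-increasing and fits are scale-equivariant", {
  qs <- quick_schedule(4, 4, seed = 7)
  gains <- tuning_amplitudes(90, 35, 0.8, 1.5, 0.3, qs$schedule$directions,
                             noise_sd = 0.1, seed = 8)
  y <- forward_trace(qs$schedule, qs$times, gains, noise_sd = 0.1, seed = 9)
  fit <- fit_kernel_scaling(y, qs$schedule, qs$times)
  expect_true(all(diff(fit$mse_path) <= 1e-10))
  fit3 <- fit_kernel_scaling(3 * y, qs$schedule, qs$times)
  expect_equal(fit3$scalings, 3 * fit$scalings, tolerance = 1e-6)
  expect_equal(fit3$kernel, fit$kernel, tolerance = 1e-6)
})

test_that("kernel-step and scaling-step solutions match a dense QR oracle", {
  qs <- quick_schedule(4, 2, seed = 10)
  set.seed(11)
  y <- forward_trace(qs$schedule, qs$times,
                     runif(length(qs$schedule$trial_onsets), 0.5, 2),
                     noise_sd = 0.2, seed = 12)
  n <- length(y)
  ctx <- retistate:::ks_context(qs$schedule, qs$times)
  # one alternation step with scalings = 1: kernel step oracle
  X <- matrix(0, n, ctx$klen)
  for (i in seq_len(ctx$n_trials)) {
    rows <- ctx$idx[, i]
    X[cbind(rows, seq_len(ctx$klen))] <- X[cbind(rows, seq_len(ctx$klen))] + 1
  }
  oracle_k <- qr.coef(qr(cbind(1, X)), y)
  fit1 <- retistate:::ks_fit(y, ctx, max_iter = 1)
  # the normalized kernel must be proportional to the oracle kernel step
  expect_gt(abs(cor(oracle_k[-1], fit1$kernel)), 1 - 1e-8)
  # scaling step oracle given the (normalized) kernel
  kern <- fit1$kernel
  Xs <- matrix(0, n, ctx$n_trials)
  for (i in seq_len(ctx$n_trials)) Xs[ctx$idx[, i], i] <- kern
  or2 <- qr.coef(qr(cbind(1, Xs)), y)
  expect_equal(unname(or2[-1]), fit1$scalings, tolerance = 1e-6)
  expect_equal(unname(or2[1]), fit1$intercept, tolerance = 1e-6)
})

test_that("responsiveness shift test separates signal from noise", {
  qs <- quick_schedule(4, 4, seed = 13)
  gains <- tuning_amplitudes(0, 40, 0.7, 2, 0.5, qs$schedule$directions)
  y <- forward_trace(qs$schedule, qs$times, gains, noise_sd = 0.2, seed = 14)
  r <- test_responsiveness(y, qs$schedule, qs$times, n_shifts = 99, seed = 1)
  expect_true(r$responsive)

  set.seed(15)
  ynull <- ar_noise(length(qs$times), ar = 0.9, sd = 0.3)
  rn <- test_responsiveness(ynull, qs$schedule, qs$times, n_shifts = 99,
                            seed = 2)
  expect_gt(rn$p, 0.025)

  expect_error(test_responsiveness(y, qs$schedule, qs$times, n_shifts = 10),
               class = "retistate_invalid")
  expect_error(test_responsiveness(rep(1, length(qs$times)), qs$schedule,
                                   qs$times),
               class = "retistate_degenerate")
})

test_that("pupil-state labels follow the strict-majority median rule", {
  dt <- 0.133
  times <- seq(0, 200, by = dt)
  mkbeh <- function(pupil) list(times = times, pupil_area = pupil,
                                blink_mask = rep(FALSE, length(times)))
  sch <- simulate_grating_schedule(4, 4, 2, c(3, 5), seed = 1, t_start = 5)

  # constant pupil: no sample strictly below the median -> all large
  lab <- classify_trials_by_pupil(mkbeh(rep(2, length(times))), sch)
  expect_true(all(lab$pupil_state == "large"))

  # first half small, second half large
  pupil <- ifelse(times < 100, 1, 3)
  lab2 <- classify_trials_by_pupil(mkbeh(pupil), sch)
  first <- sch$trial_onsets + 2 <= 100
  second <- sch$trial_onsets >= 100
  expect_true(all(lab2$pupil_state[first] == "small"))
  expect_true(all(lab2$pupil_state[second] == "large"))

  # exactly half the samples below threshold -> large (tie rule)
  beh3 <- mkbeh(rep(2, length(times)))
  sel <- which(times >= sch$trial_onsets[1] & times < sch$trial_onsets[1] + 2)
  half <- sel[seq_len(floor(length(sel) / 2))]
  beh3$pupil_area[half] <- 0.5
  beh3$pupil_area[1:3] <- 0.4   # keep the global median at 2
  lab3 <- classify_trials_by_pupil(beh3, sch)
  expect_equal(lab3$pupil_state[1], "large")

  # fully blink-masked trial -> NA
  beh4 <- mkbeh(rep(2, length(times)))
  beh4$blink_mask[times >= sch$trial_onsets[1] - 0.2 &
                  times < sch$trial_onsets[1] + 2.2] <- TRUE
  lab4 <- classify_trials_by_pupil(beh4, sch)
  expect_true(is.na(lab4$pupil_state[1]))
})

test_that("firing rates use half-open stimulus intervals", {
  sch <- list(trial_onsets = c(10, 20), trial_duration = 2)
  expect_equal(firing_rate_responses(numeric(0), sch), c(0, 0))
  expect_equal(firing_rate_responses(seq(10.1, 11.9, length.out = 10), sch),
               c(5, 0))
  # spike exactly at offset is not counted; at onset it is
  expect_equal(firing_rate_responses(c(10, 12), sch), c(0.5, 0))
})
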