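test_that("grating schedules are balanced, ordered and correctly timed", {
  sch <- simulate_grating_schedule(12, 15, 2.0, c(3, 6), seed = 7)
  expect_length(sch$trial_onsets, 180)
  expect_true(all(table(sch$directions) == 15))
  expect_true(all(diff(sch$trial_onsets) >= 2 + 3 - 1e-9))
  expect_true(all(diff(sch$trial_onsets) <= 2 + 6 + 1e-9))
  expect_equal(sort(unique(sch$directions)), seq(0, 330, by = 30))

  # degenerate ITI range gives exactly equal gaps
  s2 <- simulate_grating_schedule(4, 2, 2.0, c(3, 3), seed = 1)
  expect_equal(diff(s2$trial_onsets), rep(5, 7), tolerance = 1e-12)

  # laser doubling, balanced across conditions (short-trial variant)
  s3 <- simulate_grating_schedule(8, 5, 0.5, c(0.5, 1.0), with_laser = TRUE,
                                  seed = 3)
  expect_length(s3$trial_onsets, 80)
  expect_equal(sum(s3$laser_on), 40)
  expect_true(all(table(s3$directions, s3$laser_on) == 5))

  expect_error(simulate_grating_schedule(12, 15, 2, c(-1, 6)),
               class = "retistate_invalid")
  expect_error(simulate_grating_schedule(3, 15, 2, c(3, 6)),
               class = "retistate_invalid")
})

test_that("sparse-noise movies match requested probabilities", {
  nm <- simulate_noise_movie(c(10, 27), 600, 0.01, 0.01, 6, seed = 5)
  expect_equal(dim(nm$frames)[3], 3600)
  expect_true(all(nm$frames %in% c(-1, 0, 1)))
  wf <- mean(nm$frames == 1)
  bf <- mean(nm$frames == -1)
  expect_gt(wf, 0.008); expect_lt(wf, 0.012)
  expect_gt(bf, 0.008); expect_lt(bf, 0.012)

  allgray <- simulate_noise_movie(c(4, 4), 10, 0, 0, 6, seed = 1)
  expect_true(all(allgray$frames == 0))

  nogray <- simulate_noise_movie(c(4, 4), 10, 0.5, 0.5, 6, seed = 2)
  expect_equal(dim(nogray$frames)[3], 60)
  expect_true(all(nogray$frames != 0))

  expect_error(simulate_noise_movie(c(4, 4), 10, -0.1, 0.1),
               class = "retistate_invalid")
  expect_error(simulate_noise_movie(c(4, 4), 10, 0.6, 0.6),
               class = "retistate_invalid")
})

test_that("behavior generator is seeded, rectified and coupling-controlled", {
  b1 <- simulate_behavior(600, 0.133, 0.5, seed = 4)
  b2 <- simulate_behavior(600, 0.133, 0.5, seed = 4)
  expect_identical(b1, b2)
  expect_true(all(b1$running_speed >= 0))
  expect_true(all(b1$pupil_area[!b1$blink_mask] > 0))
  expect_lt(mean(b1$blink_mask), 0.02)
  expect_true(all(diff(b1$times) > 0))

  b3 <- simulate_behavior(600, 0.133, 0.9, seed = 2)
  expect_gt(cor(b3$running_speed, b3$pupil_area), 0.4)

  expect_error(simulate_behavior(30, 0.133, 0.5), class = "retistate_invalid")
  expect_error(simulate_behavior(600, -1, 0.5), class = "retistate_invalid")
})

test_that("uncoupled running and pupil stay within the shift-test null band", {
  hits <- vapply(1:20, function(s) {
    b <- simulate_behavior(600, 0.133, 0, seed = s)
    st <- shift_test(b$running_speed, b$pupil_area, n_shifts = 200,
                     dt = 0.133, seed = s)
    st$significant
  }, logical(1))
  expect_lte(mean(hits), 0.10)
})

test_that("session synthesis is deterministic and honors the forward model", {
  beh <- simulate_behavior(300, 0.133, 0.5, seed = 1)
  sch <- simulate_grating_schedule(4, 4, 2, c(3, 5), seed = 2, t_start = 5)
  u <- ground_truth_unit(theta_p = 45, sigma = 35, ds = 0.8, alpha_true = 0.6)
  s1 <- synthesize_session(list(u), beh, sch, noise_sd = 0.05, seed = 3)
  s2 <- synthesize_session(list(u), beh, sch, noise_sd = 0.05, seed = 3)
  expect_identical(s1$raw_F, s2$raw_F)
  expect_identical(s1$raw_N, s2$raw_N)

  expect_error(synthesize_session(list(), beh, sch),
               class = "retistate_invalid")

  # noiseless, contamination-free synthesis reproduces the latent model
  u0 <- ground_truth_unit(theta_p = 45, sigma = 35, ds = 0.8, alpha_true = 0)
  s0 <- synthesize_session(list(u0), beh, sch, noise_sd = 0, seed = 3)
  fit <- fit_kernel_scaling(s0$raw_F[, 1] - mean(s0$raw_F[, 1]), sch,
                            beh$times)
  labels <- classify_trials_by_pupil(beh, sch)
  gains <- wrapped_double_gaussian(sch$directions,
                                   tuning_params(45, 1, 35, 0.8, 0))
  expect_gt(cor(fit$scalings, gains), 0.999)
})

test_that("suppressed units receive negated stimulus gains", {
  beh <- simulate_behavior(300, 0.133, 0.5, seed = 1)
  sch <- simulate_grating_schedule(4, 4, 2, c(3, 5), seed = 2, t_start = 5)
  up <- ground_truth_unit(theta_p = 0, sigma = 35, ds = 1, alpha_true = 0)
  us <- ground_truth_unit(theta_p = 0, sigma = 35, ds = 1, alpha_true = 0,
                          suppressed = TRUE)
  ss <- synthesize_session(list(up, us), beh, sch, noise_sd = 0, seed = 3)
  lat_p <- ss$raw_F[, 1] - mean(ss$raw_F[, 1])
  lat_s <- ss$raw_F[, 2] - mean(ss$raw_F[, 2])
  expect_lt(cor(lat_p, lat_s), -0.95)
})

test_that("photoisomerization formula evaluates literally", {
  expect_equal(photoisomerization_rate(s_pupil = 0), 0)
  r1 <- photoisomerization_rate(s_pupil = 3.2)
  r2 <- photoisomerization_rate(s_pupil = 0.1)
  expect_equal(r1 / r2, 32, tolerance = 1e-12)
  hand <- pi * 83 * 1500 * 0.7 * (0.1 / 18) * 1
  expect_equal(photoisomerization_rate(83, 0.7, 0.1, 18, 1), hand,
               tolerance = 1e-12)
  expect_error(photoisomerization_rate(irradiance_I = -1),
               class = "retistate_invalid")
})

test_that("sessions round-trip through the CSV container", {
  beh <- simulate_behavior(120, 0.133, 0.5, seed = 1)
  sch <- simulate_grating_schedule(4, 2, 2, c(3, 4), seed = 2, t_start = 5)
  u <- ground_truth_unit(theta_p = 10, sigma = 30, ds = 0.5)
  ses <- synthesize_session(list(u), beh, sch, noise_sd = 0.1, seed = 3,
                            n_axons = 1)
  d <- file.path(tempdir(), "sess_io")
  write_session(ses, d)
  back <- read_session(d)
  expect_equal(back$raw_F[, 1], ses$raw_F[, 1], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$gratings$directions, ses$gratings$directions)
  expect_equal(back$behavior$pupil_area, ses$behavior$pupil_area,
               tolerance = 1e-12)
  expect_equal(back$ground_truth[[1]]$theta_p, 10)
  expect_equal(length(back$spikes), 1)
  unlink(d, recursive = TRUE)
})
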