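test_that("the epoch grid has the documented arithmetic: 541 samples at 200 Hz", {
  tt <- fix_trials(1, 16, seed = 41)
  ep <- simulate_meg_epochs(tt, n_sensors = 2, sampling_rate_hz = 200,
                            span_stim_ms = c(-200, 2500), seed = 42)
  expect_length(ep$times_ms, 541)
  expect_equal(diff(ep$times_ms)[1], 5)
  expect_equal(range(ep$times_ms), c(-200, 2500))
  expect_equal(dim(ep$values)[1], sum(!tt$omitted))
})

test_that("response-aligned epochs are the stimulus-aligned series shifted by RT", {
  tt <- fix_trials(1, 16, seed = 43,
                   behaviour_params = list(omission_rate = 0))
  step <- 1000 / 20
  # on-grid RTs: the shift is exact
  tt$rt_ms <- rep(1600, nrow(tt))
  both <- simulate_meg_epochs(tt, n_sensors = 3,
                              list(effect_spec("across", 1, window_ms = c(100, 600))),
                              alignment = "both", sampling_rate_hz = 20,
                              span_stim_ms = c(-200, 1000),
                              span_resp_ms = c(-2000, 200), seed = 44)
  i_resp <- which(both$response$times_ms == -1600)
  i_stim <- which(both$stimulus$times_ms == 0)
  expect_equal(both$response$values[, , i_resp], both$stimulus$values[, , i_stim])
  # off-grid RTs: interpolating the response epoch at -RT recovers the
  # stimulus-aligned signal at t = 0 (low noise so interpolation error is
  # set by the smooth envelope, not by the noise floor)
  tt$rt_ms <- rep(1612.3, nrow(tt))
  both <- simulate_meg_epochs(tt, n_sensors = 3,
                              list(effect_spec("across", 1, window_ms = c(-100, 900))),
                              alignment = "both", sampling_rate_hz = 20,
                              span_stim_ms = c(-200, 1000),
                              span_resp_ms = c(-2000, 200),
                              noise_sd = 1e-8, seed = 45)
  tr_i <- 1
  at <- approx(both$response$times_ms, both$response$values[tr_i, 1, ],
               xout = -1612.3)$y
  expect_equal(at, both$stimulus$values[tr_i, 1, which(both$stimulus$times_ms == 0)],
               tolerance = 0.02)
})

test_that("planted effects decode only inside their window", {
  tt <- fix_trials(4, 16, seed = 46,
                   behaviour_params = list(accuracy_rate = 1, omission_rate = 0))
  ep <- fix_epochs(tt, effect = 3, window = c(300, 700), n_sensors = 12,
                   rate = 20, span = c(-200, 1000), seed = 47)
  lab <- fix_meg_labels(ep, tt)
  r <- decode_meg_timecourse(ep, lab, k = 5, seed = 48)
  pre <- r$accuracy[r$times_ms < 300]
  inside <- r$accuracy[r$times_ms >= 350 & r$times_ms <= 650]
  n_te <- sum(!is.na(lab))
  ci <- 0.5 + 2.6 * sqrt(0.25 / n_te)
  expect_lt(mean(pre > ci), 0.2)
  expect_true(all(inside > 0.75))
})

test_that("zero-signal epochs decode at chance at nearly all time points", {
  tt <- fix_trials(4, 16, seed = 49,
                   behaviour_params = list(accuracy_rate = 1, omission_rate = 0))
  ep <- fix_epochs(tt, effect = 0, n_sensors = 8, rate = 20,
                   span = c(-200, 1000), seed = 50)
  lab <- fix_meg_labels(ep, tt)
  r <- decode_meg_timecourse(ep, lab, k = 5, seed = 51)
  n_te <- length(lab)
  # cross-validated accuracies vary a little more than the raw binomial
  # (training folds are random too); use a 99% normal band on the test count
  ci <- 2.58 * sqrt(0.25 / n_te)
  expect_gte(mean(abs(r$accuracy - 0.5) <= ci + 0.02), 0.9)
  expect_lt(abs(mean(r$accuracy) - 0.5), 0.02)
})

test_that("a time-constant signal gives a near-flat accuracy trace", {
  tt <- fix_trials(4, 16, seed = 52,
                   behaviour_params = list(accuracy_rate = 1, omission_rate = 0))
  specs <- list(effect_spec("across", 1.5))  # no window: always on
  ep <- simulate_meg_epochs(tt, 8, specs, sampling_rate_hz = 20,
                            span_stim_ms = c(-200, 1000), seed = 53)
  lab <- fix_meg_labels(ep, tt)
  r <- decode_meg_timecourse(ep, lab, k = 5, seed = 54)
  se <- sqrt(mean(r$accuracy) * (1 - mean(r$accuracy)) / length(lab))
  expect_lt(sd(r$accuracy), 2 * se)
})

test_that("epochs are seed-reproducible and drop omitted trials", {
  tt <- generate_trial_sequence(2, 16, seed = 55,
                                behaviour_params = list(omission_rate = 0.3))
  a <- fix_epochs(tt, seed = 56)
  b <- fix_epochs(tt, seed = 56)
  expect_identical(a$values, b$values)
  expect_equal(a$trial_ids, tt$trial_id[!tt$omitted])
})

test_that("effect windows outside the epoch span are rejected", {
  tt <- fix_trials(1, 16, seed = 57)
  expect_error(
    simulate_meg_epochs(tt, 4, list(effect_spec("across", 1, window_ms = c(2000, 3000))),
                        sampling_rate_hz = 20, span_stim_ms = c(-200, 2500)),
    "outside the stimulus-aligned epoch span")
  expect_error(
    simulate_meg_epochs(tt, 4, noise_sd = 0), "noise_sd must be positive")
})
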