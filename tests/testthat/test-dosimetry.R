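test_that("the mean participant calibrates to the 8.1 degC unit dose", {
  p <- fixed_participant()
  dev <- noise_free("low")
  b <- simulate_bout(p, regimen("hold_hr", 100, duration = 30), dev,
                     date = "2015-03-02", seed = 1)
  rx <- calibrate_dose(b, detect_fatigue(b, dev))
  expect_equal(rx$threshold_c, 8.1, tolerance = 0.05)
  expect_identical(rx$participant_id, "T1")
})

test_that("calibration is refused for fatigued, short or high-sensitivity bouts", {
  p <- fixed_participant()
  dev <- device_params("low")
  good <- simulate_bout(p, regimen("hold_hr", 100, duration = 30), dev,
                        date = "2015-03-02", seed = 2)
  fa_bad <- structure(list(fatigue_free = FALSE, mechanism = "lwo_decline_steady_hr",
                           onset_minute = 12), class = "fatigue_assessment")
  expect_error(calibrate_dose(good, fa_bad), "fatigue-free")
  short <- simulate_bout(p, regimen("hold_hr", 100, duration = 20), dev,
                         date = "2015-03-02", seed = 3)
  expect_error(calibrate_dose(short, detect_fatigue(short, dev)),
               "at least 30 minutes")
  devh <- device_params("high")
  high <- simulate_bout(p, regimen("hold_hr", 100, duration = 30), devh,
                        date = "2015-03-02", seed = 4)
  expect_error(calibrate_dose(high, detect_fatigue(high, devh)),
               "low-sensitivity")
})

test_that("a seeded 7-participant cohort brackets the observed dose range", {
  co <- make_cohort(7, 0.17, seed = 1)
  dev <- device_params("low")
  doses <- sapply(seq_along(co), function(i) {
    b <- simulate_bout(co[[i]], regimen("hold_hr", 100, duration = 30), dev,
                       date = "2015-03-02", seed = 100 + i)
    calibrate_dose(b, detect_fatigue(b, dev))$threshold_c
  })
  expect_true(all(doses >= 6 & doses <= 11))
})

test_that("threshold crossings interpolate linearly on an exact ramp", {
  tr <- sensor_trace(0:35, (0:35) / 3, mode = "low")
  ev <- track_dose(tr, list(participant_id = "X", threshold_c = 10), "14:00")
  expect_identical(ev$t_half, 15)
  expect_identical(ev$t_full, 30)
  expect_identical(ev$notified_at, "14:30")
  expect_true(ev$completed)
  # exact split-half symmetry on linear traces
  expect_identical(ev$t_full, 2 * ev$t_half)
})

test_that("incomplete doses and non-zeroed traces are handled", {
  tr <- sensor_trace(0:20, (0:20) / 10, mode = "low")
  ev <- track_dose(tr, list(threshold_c = 10), "14:00")
  expect_false(ev$completed)
  expect_true(is.na(ev$t_full))
  expect_true(is.na(ev$notified_at))
  bad <- data.frame(minute = 0:10, delta_t_c = 1 + (0:10) / 3)
  expect_error(track_dose(bad, list(threshold_c = 5)), "baseline")
})

test_that("dose events are idempotent and monotone in the threshold", {
  p <- fixed_participant(power_scale = 10 / 8.1)
  dev <- device_params("low")
  b <- simulate_bout(p, dose_regimen(12), dev, date = "2015-06-01",
                     clock_time = "14:00", seed = 5)
  e1 <- track_dose(b$sensor, list(threshold_c = 10), "14:00")
  e2 <- track_dose(b$sensor, list(threshold_c = 10), "14:00")
  expect_identical(e1, e2)
  fulls <- sapply(c(4, 6, 8, 10), function(th) {
    track_dose(b$sensor, list(threshold_c = th), "14:00")$t_full
  })
  expect_true(all(diff(fulls) >= 0))
})

test_that("dose fractions scale with duration against the 30-min reference", {
  expect_identical(dose_fraction(15), 0.5)
  expect_identical(dose_fraction(30), 1.0)
  expect_identical(dose_fraction(60), 2.0)
  expect_identical(dose_fraction(45, 45), 1)
  expect_error(dose_fraction(0), "> 0")
})

test_that("consecutive doses without recovery take longer the second time", {
  # second bout started fatigued: model as an evening-factor advanced onset
  p <- fixed_participant(power_scale = 10 / 8.1)
  dev <- noise_free("low")
  first <- simulate_bout(p, dose_regimen(10), dev, date = "2015-06-01",
                         clock_time = "14:00", seed = 6)
  carry <- simulate_bout(p, dose_regimen(10), dev, date = "2015-06-01",
                         clock_time = "19:00", seed = 6)
  t1 <- track_dose(first$sensor, list(threshold_c = 10), "14:00")$t_full
  t2 <- track_dose(carry$sensor, list(threshold_c = 10), "19:00")$t_full
  expect_gt(t2, t1)
})

test_that("a multi-day recording splits into re-zeroed sessions", {
  p <- fixed_participant(power_scale = 10 / 8.1)
  dev <- device_params("low")
  sched <- program_schedule(n_days = 5,
                            day_windows = c("afternoon", "skip", "evening",
                                            "afternoon", "skip"), seed = 9)
  prog <- simulate_program(p, sched, dose_regimen(10), dev)
  sessions <- split_sessions(prog$continuous)
  expect_length(sessions, 3)
  for (s in sessions) expect_identical(s$delta_t_c[1], 0)
})
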