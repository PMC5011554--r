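test_that("a moderate 30-min bout with fatigue beyond its end is flat and fatigue-free", {
  p <- fixed_participant()
  dev <- noise_free("low")
  b <- simulate_bout(p, regimen("hold_hr", 100, duration = 30), dev,
                     date = "2015-03-02", seed = 1)
  # onset at HR 100 is 7 + 0.8 * 30 = 31 min > bout duration
  expect_true(is.na(b$fatigue_onset))
  expect_equal(unique(b$power$power), b$power$power[1])
  expect_equal(detect_fatigue(b, dev)$fatigue_free, TRUE)
  expect_equal(mean(b$hr$bpm), 100, tolerance = 5)
})

test_that("planted fatigue onsets follow the linear heart-rate-deficit law", {
  p <- fixed_participant()
  dev <- noise_free("high")
  b130 <- simulate_bout(p, regimen("hold_hr", 130, duration = 20), dev,
                        date = "2015-03-02", seed = 2)
  b120 <- simulate_bout(p, regimen("hold_hr", 120, duration = 30), dev,
                        date = "2015-03-02", seed = 3)
  expect_equal(b130$fatigue_onset, 7)
  expect_equal(b120$fatigue_onset, 15)
  # power declines after onset, held before it
  expect_equal(b130$power$power[1:7], rep(b130$power$power[1], 7))
  expect_true(all(diff(b130$power$power[8:20]) < 1e-12))
  expect_lt(b130$power$power[20], b130$power$power[1])
})

test_that("held work rate makes the heart rate drift toward HRmax after onset", {
  p <- fixed_participant(fatigue_onset_ref = 10, fatigue_slope = 0)
  dev <- noise_free("high")
  b <- simulate_bout(p, regimen("hold_power", 1.0, duration = 45), dev,
                     date = "2015-03-02", seed = 4)
  expect_equal(b$fatigue_onset, 10)
  expect_equal(unique(b$power$power), b$power$power[1])
  early <- mean(b$hr$bpm[b$hr$minute < 10])
  late <- mean(b$hr$bpm[b$hr$minute > 35])
  expect_gt(late, early + 20)
  expect_true(all(b$hr$bpm <= 230))
})

test_that("dose_reached bouts stop one sample past the threshold or flag timeout", {
  p <- fixed_participant(power_scale = 10 / 8.1)
  dev <- noise_free("low")
  b <- simulate_bout(p, dose_regimen(10), dev, date = "2015-06-01",
                     clock_time = "14:00", seed = 5)
  expect_false(b$timeout)
  n <- nrow(b$sensor)
  expect_gte(b$sensor$delta_t_c[n - 1], 10)
  expect_lt(b$sensor$delta_t_c[n - 3], 10)
  # an unreachable dose within the 120-min cap is flagged
  weak <- fixed_participant(power_scale = 0.6)
  b2 <- simulate_bout(weak, dose_regimen(25), dev, date = "2015-06-01",
                      clock_time = "14:00", seed = 6)
  expect_true(b2$timeout)
})

test_that("evening sessions advance onset and steepen the decay", {
  p <- fixed_participant()
  dev <- noise_free("low")
  aft <- simulate_bout(p, regimen("hold_hr", 100, duration = 40), dev,
                       date = "2015-06-01", clock_time = "14:00", seed = 7)
  eve <- simulate_bout(p, regimen("hold_hr", 100, duration = 40), dev,
                       date = "2015-06-01", clock_time = "19:00", seed = 7)
  expect_false(aft$evening)
  expect_true(eve$evening)
  expect_equal(eve$fatigue_onset, 31 / p$evening_factor, tolerance = 1e-9)
  expect_lt(sum(eve$power$power), sum(aft$power$power))
})

test_that("identical seeds reproduce bouts bit-for-bit at CSV precision", {
  p <- participant("P1")  # includes day-to-day variability
  dev <- device_params("low")
  a <- simulate_bout(p, regimen("hold_hr", 100, duration = 30), dev,
                     date = "2015-03-02", seed = 11)
  b <- simulate_bout(p, regimen("hold_hr", 100, duration = 30), dev,
                     date = "2015-03-02", seed = 11)
  expect_identical(round(a$sensor$delta_t_c, 3), round(b$sensor$delta_t_c, 3))
  expect_identical(a$hr$bpm, b$hr$bpm)
  c <- simulate_bout(p, regimen("hold_hr", 100, duration = 30), dev,
                     date = "2015-03-02", seed = 12)
  expect_false(identical(a$sensor$delta_t_c, c$sensor$delta_t_c))
})

test_that("a cooldown tail records the recovery phase", {
  p <- fixed_participant()
  dev <- noise_free("high")
  b <- simulate_bout(p, regimen("hold_hr", 100, duration = 20), dev,
                     date = "2015-03-02", seed = 8, cooldown = 10)
  expect_equal(b$duration, 20)
  expect_equal(nrow(b$sensor), 31)
  # temperature falls and HR relaxes toward rest after cessation
  expect_lt(b$sensor$delta_t_c[31], b$sensor$delta_t_c[21] * 0.2)
  expect_lt(b$hr$bpm[31], 80)
})
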