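test_that("fatigue-free construction is classified fatigue-free", {
  p <- fixed_participant()
  dev <- device_params("low")
  b <- simulate_bout(p, regimen("hold_hr", 100, duration = 30), dev,
                     date = "2015-03-02", seed = 1)
  fa <- detect_fatigue(b, dev)
  expect_true(fa$fatigue_free)
  expect_identical(fa$mechanism, "none")
  expect_true(is.na(fa$onset_minute))
})

test_that("work-output decline at steady heart rate is detected near the planted onset", {
  p <- fixed_participant()
  dev <- device_params("high")
  b <- simulate_bout(p, regimen("hold_hr", 120, duration = 30), dev,
                     date = "2015-03-02", seed = 2)
  fa <- detect_fatigue(b, dev)
  expect_identical(fa$mechanism, "lwo_decline_steady_hr")
  expect_equal(fa$onset_minute, 15, tolerance = 2)
  expect_true(fa$hr_steady)
})

test_that("heart-rate rise at steady work output is detected near the planted onset", {
  p <- fixed_participant(fatigue_onset_ref = 12, fatigue_slope = 0)
  dev <- device_params("high")
  b <- simulate_bout(p, regimen("hold_power", 1.0, duration = 45), dev,
                     date = "2015-03-02", seed = 3)
  fa <- detect_fatigue(b, dev)
  expect_identical(fa$mechanism, "hr_rise_steady_lwo")
  expect_equal(fa$onset_minute, 12, tolerance = 2.5)
  expect_true(fa$lwo_steady)
})

test_that("a missing heart-rate trace yields a partial, LWO-only assessment", {
  p <- fixed_participant()
  dev <- device_params("high")
  b <- simulate_bout(p, regimen("hold_hr", 130, duration = 20), dev,
                     date = "2015-03-02", seed = 4)
  b$hr <- NULL
  fa <- detect_fatigue(b, dev)
  expect_true(fa$partial)
  expect_identical(fa$mechanism, "lwo_decline_steady_hr")
})

test_that("planted onsets are recovered within 2 minutes across replicates", {
  p <- fixed_participant()
  dev <- device_params("high")
  errs <- sapply(1:50, function(s) {
    target <- if (s %% 2 == 0) 130 else 120
    dur <- if (target == 130) 20 else 30
    b <- simulate_bout(p, regimen("hold_hr", target, duration = dur), dev,
                       date = "2015-03-02", seed = 500 + s)
    detect_fatigue(b, dev)$onset_minute - b$fatigue_onset
  })
  expect_true(all(abs(errs) <= 2))
})

test_that("detected onset equals the brute-force scan on noise-free traces", {
  p <- fixed_participant()
  dev <- noise_free("high")
  for (s in 1:5) {
    b <- simulate_bout(p, regimen("hold_hr", 120, duration = 30), dev,
                       date = "2015-03-02", seed = 40 + s)
    fa <- detect_fatigue(b, dev)
    # literal re-derivation of the smoothed power path and scan
    ex <- b$sensor[b$sensor$minute <= b$duration, ]
    ph <- estimate_power(sensor_trace(ex$minute, ex$delta_t_c, "high"), dev, 3)$power
    p_sm <- sapply(seq_along(ph), function(i) {
      mean(ph[max(1, i - 1):min(length(ph), i + 1)])
    })
    interior <- 3:(length(p_sm) - 2)
    base <- max(median(p_sm[interior[1:5]]), median(p_sm[interior[6:10]]))
    oracle <- oracle_lwo_onset(p_sm, ex$minute, interior, base)
    expect_equal(fa$onset_minute, oracle)
  }
})

test_that("tightening the drop tolerance never delays the detected onset", {
  p <- fixed_participant()
  dev <- noise_free("high")
  b <- simulate_bout(p, regimen("hold_hr", 120, duration = 30), dev,
                     date = "2015-03-02", seed = 6)
  crit <- study_defaults()$analysis
  onsets <- sapply(c(0.12, 0.08, 0.05, 0.03), function(tol) {
    crit$lwo_drop_tol <- tol
    detect_fatigue(b, dev, criteria = crit)$onset_minute
  })
  expect_true(all(diff(onsets) <= 1e-9))
})

test_that("steady-state duration shortens as intensity rises across the cohort", {
  dev <- device_params("high")
  co <- make_cohort(5, 0.17, seed = 10)
  steady_at <- function(target, dur) {
    mean(sapply(seq_along(co), function(i) {
      b <- simulate_bout(co[[i]], regimen("hold_hr", target, duration = dur),
                         dev, date = "2015-03-02", seed = 600 + i)
      on <- detect_fatigue(b, dev)$onset_minute
      if (is.na(on)) dur else on
    }))
  }
  s130 <- steady_at(130, 20)
  s120 <- steady_at(120, 30)
  s100 <- steady_at(100, 30)
  expect_lt(s130, s120)
  expect_lt(s120, s100)
})
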