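test_that("zero drive produces a zero trace and validation catches bad input", {
  dev <- noise_free("high")
  tr <- simulate_temperature(power_trace(0:19, rep(0, 20)), dev, noise_sd = 0)
  expect_equal(tr$delta_t_c, rep(0, 21))
  expect_error(power_trace(0:4, c(1, 1, -0.2, 1, 1)), "non-negative")
  expect_error(sensor_trace(c(0, 1, 3, 4), rep(0, 4), "low"), "1-minute grid")
  expect_error(device_params("high", euler_step = 0), "euler_step")
  expect_error(device_params("low", cooling_lambda = 0.05), "quasi-linear")
  expect_error(device_params("high", cooling_lambda = 0.001), "plateau")
})

test_that("constant drive matches the closed-form solution and its plateau", {
  # high mode: plateau alpha*P/lambda = 34.2 degC for the mean participant
  dev <- noise_free("high")
  expect_equal(steady_state_delta(1.0, dev), 34.2, tolerance = 1e-9)
  expect_equal(steady_state_delta(1.5, dev), 51.3, tolerance = 1e-9)
  expect_equal(steady_state_delta(0, dev), 0)
  expect_error(steady_state_delta(1, device_params("low", cooling_lambda = 0)),
               "no steady state")

  tr <- simulate_temperature(power_trace(0:59, rep(1, 60)), dev, noise_sd = 0)
  expect_equal(tail(tr$delta_t_c, 1), 34.2, tolerance = 0.01)

  # explicit low-sensitivity parameterization from the worked example:
  # alpha=0.3125, lambda=0.01 gives (alpha/lambda)(1-e^-0.3) ~ 8.1 at 30 min
  dev2 <- device_params("low", gain_alpha = 0.3125, cooling_lambda = 0.01,
                        noise_sd = 0)
  tr2 <- simulate_temperature(power_trace(0:29, rep(1, 30)), dev2, noise_sd = 0)
  expect_equal(tail(tr2$delta_t_c, 1),
               closed_form_delta(30, 1, 0.3125, 0.01), tolerance = 0.01)
  expect_equal(tail(tr2$delta_t_c, 1), 8.1, tolerance = 0.05)
})

test_that("euler integration agrees with the closed form within 0.5%", {
  for (mode in c("high", "low")) {
    dev <- device_params(mode, noise_sd = 0, euler_step = 0.1)
    for (P in c(0.7, 1.0, 1.6)) {
      tr <- simulate_temperature(power_trace(0:44, rep(P, 45)), dev, noise_sd = 0)
      expected <- closed_form_delta(tr$minute, P, dev$gain_alpha, dev$cooling_lambda)
      idx <- tr$minute >= 1
      expect_lt(max(abs(tr$delta_t_c[idx] - expected[idx]) / expected[idx]), 0.005)
    }
  }
})

test_that("constant-drive traces are nondecreasing and bounded by the plateau", {
  for (mode in c("high", "low")) {
    dev <- device_params(mode, noise_sd = 0)
    tr <- simulate_temperature(power_trace(0:89, rep(1.2, 90)), dev, noise_sd = 0)
    expect_true(all(diff(tr$delta_t_c) >= -1e-12))
    expect_true(all(tr$delta_t_c <= steady_state_delta(1.2, dev) + 1e-9))
  }
})

test_that("low-sensitivity rise is quasi-linear (dose proportional to duration)", {
  dev <- noise_free("low")
  stopifnot(dev$cooling_lambda * 30 <= 0.3)
  tr <- simulate_temperature(power_trace(0:59, rep(1, 60)), dev, noise_sd = 0)
  lin <- dev$gain_alpha * 1 * tr$minute
  idx <- tr$minute %in% c(15, 30, 60)
  expect_true(all(abs(tr$delta_t_c[idx] - lin[idx]) / lin[idx] < 0.15))
  # duration ratios 15/30/60 min -> 0.5/1.0/2.0 doses within 8%
  d <- tr$delta_t_c[match(c(15, 30, 60), tr$minute)]
  expect_equal(d[1] / d[2], 0.5, tolerance = 0.08)
  expect_equal(d[3] / d[2], 2.0, tolerance = 0.08)
})

test_that("noise is seed-reproducible and never breaks the zero baseline", {
  dev <- device_params("low")
  p <- power_trace(0:29, rep(1, 30))
  t1 <- simulate_temperature(p, dev, seed = 42)
  t2 <- simulate_temperature(p, dev, seed = 42)
  expect_identical(t1$delta_t_c, t2$delta_t_c)
  expect_identical(t1$delta_t_c[1], 0)
  expect_gt(sd(t1$delta_t_c - simulate_temperature(p, dev, noise_sd = 0)$delta_t_c), 0)
})
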