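test_that("split-half times satisfy the exact additive identity", {
  expect_identical(split_half_times(list(completed = TRUE, t_half = 15,
                                         t_full = 30)),
                   c(t_first = 15, t_second = 15))
  # the observed evening means: halves 13.5 and 20.3 summing to 33.8
  halves <- split_half_times(list(completed = TRUE, t_half = 13.5,
                                  t_full = 33.8))
  expect_equal(unname(halves), c(13.5, 20.3))
  expect_identical(sum(halves), 33.8)
  expect_error(split_half_times(list(completed = FALSE)), "incomplete")
})

test_that("percent_longer is plain relative arithmetic, unit-invariant", {
  expect_identical(percent_longer(10, 10), 0)
  expect_identical(percent_longer(10, 15), 50)
  expect_equal(percent_longer(13.5, 20.3), 50.4, tolerance = 0.05)
  expect_identical(percent_longer(10, 15), percent_longer(600, 900))  # seconds
  expect_error(percent_longer(0, 5), "> 0")
})

test_that("evening bouts lengthen the second half more than afternoon bouts", {
  p <- fixed_participant("H", power_scale = 10 / 8.1)
  p2 <- participant("H", power_scale = 10 / 8.1)  # with day-to-day noise
  aft <- sapply(1:100, function(s) {
    e <- home_dose_event(p2, "14:30", seed = 1000 + s)
    split_half_times(e)
  })
  eve <- sapply(1:100, function(s) {
    e <- home_dose_event(p2, "19:00", seed = 2000 + s)
    split_half_times(e)
  })
  ratio_aft <- mean(aft[2, ]) / mean(aft[1, ])
  ratio_eve <- mean(eve[2, ]) / mean(eve[1, ])
  expect_gt(ratio_eve, ratio_aft)
})

test_that("diurnal_compare reproduces the grouped afternoon/evening pattern", {
  p <- participant("H", power_scale = 10 / 8.1)
  events <- c(
    lapply(1:20, function(s) home_dose_event(p, "14:30", seed = 3000 + s)),
    lapply(1:20, function(s) home_dose_event(p, "19:00", seed = 4000 + s))
  )
  rep <- diurnal_compare(events)
  g <- rep$groups
  expect_identical(g$n, c(20L, 20L))
  expect_lt(g$mean_total[g$group == "afternoon"],
            g$mean_total[g$group == "evening"])
  expect_gt(g$p_within[g$group == "afternoon"], 0.05)
  expect_lt(g$p_within[g$group == "evening"], 0.05)
  expect_lt(rep$between$p[rep$between$comparison == "t_total"], 0.05)
  # permutation variant agrees on the clear evening effect
  rep_perm <- diurnal_compare(events, test = "permutation")
  expect_lt(rep_perm$groups$p_within[2], 0.05)
})

test_that("identical events give unit p-values with a zero-variance flag", {
  ev <- lapply(1:6, function(i) {
    list(participant_id = "X", date = as.Date("2015-06-01") + i,
         start_clock_time = if (i <= 3) "14:00" else "19:00",
         threshold_c = 10, t_half = 15, t_full = 30, notified_at = "14:30",
         completed = TRUE)
  })
  rep <- diurnal_compare(ev)
  expect_true(all(rep$groups$p_within == 1))
  expect_match(rep$groups$flag[1], "zero-variance")
})

test_that("significance vanishes under permuted group labels", {
  p <- participant("H", power_scale = 10 / 8.1)
  events <- c(
    lapply(1:20, function(s) home_dose_event(p, "14:30", seed = 3000 + s)),
    lapply(1:20, function(s) home_dose_event(p, "19:00", seed = 4000 + s))
  )
  tab <- dose_events_table(events)
  set.seed(11)
  not_sig <- replicate(100, {
    perm <- tab
    perm$start_clock_time <- sample(perm$start_clock_time)
    r <- diurnal_compare(perm)
    r$between$p[r$between$comparison == "t_total"] >= 0.05
  })
  expect_gte(mean(not_sig), 0.90)
})

test_that("the evening split-half comparison is powered at n=20", {
  p <- participant("H", power_scale = 10 / 8.1)
  hits <- sapply(1:200, function(r) {
    halves <- sapply(1:20, function(s) {
      split_half_times(home_dose_event(p, "19:00", seed = 10000 + 20 * r + s))
    })
    t.test(halves[1, ], halves[2, ], var.equal = FALSE)$p.value < 0.05
  })
  expect_gte(mean(hits), 0.80)
})

test_that("compliance summary counts distinct notification days per week", {
  ev <- lapply(1:11, function(i) {
    list(participant_id = "H", date = as.Date("2015-06-01") + i,
         start_clock_time = "14:00", threshold_c = 10, t_half = 14,
         t_full = 28, notified_at = "14:28", completed = TRUE)
  })
  cs <- compliance_summary(ev, weeks = 15 / 7)
  expect_equal(cs$mean, 5.133333, tolerance = 1e-6)
  expect_identical(compliance_summary(list(), weeks = 1)$mean, 0)
  expect_error(compliance_summary(ev, weeks = 0), "> 0")
})
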