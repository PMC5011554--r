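# Shared fixtures and independent oracles for the test suite.

# Closed form of the first-order thermal model at constant drive:
# delta(t) = (alpha * P / lambda) * (1 - exp(-lambda * t)).
closed_form_delta <- function(t, P, alpha, lambda) {
  if (lambda == 0) return(alpha * P * t)
  (alpha * P / lambda) * (1 - exp(-lambda * t))
}

# Deterministic participant: no day-to-day work-rate variation, so planted
# physiology is exactly reproducible.
fixed_participant <- function(id = "T1", power_scale = 1, ...) {
  participant(id, age = 40, hr_rest = 62, power_scale = power_scale,
              day_to_day_cv = 0, ...)
}

noise_free <- function(mode) device_params(mode, noise_sd = 0)

# Brute-force onset scan: literal minute-by-minute implementation of the
# steadiness definition (first sustained drop below (1 - tol) * steady level,
# backdated to the start of the sustained deviation at the half-tolerance
# level). Operates on a plain numeric vector of smoothed power estimates.
oracle_lwo_onset <- function(p_sm, minutes, interior, base, tol = 0.05,
                             persistence = 3) {
  for (i in interior) {
    if (i + persistence - 1 > max(interior)) break
    run_ok <- TRUE
    for (j in i:(i + persistence - 1)) {
      if (!(p_sm[j] < (1 - tol) * base)) { run_ok <- FALSE; break }
    }
    if (run_ok) {
      k <- i
      while (k > min(interior) && p_sm[k - 1] < base * (1 - tol / 2)) k <- k - 1
      return(minutes[k])
    }
  }
  NA_real_
}

# One-call home dose-taking bout + tracking, for diurnal statistics.
home_dose_event <- function(p, clock_time, seed, threshold = 10,
                            device = device_params("low")) {
  b <- simulate_bout(p, dose_regimen(threshold), device, date = "2015-06-01",
                     clock_time = clock_time, seed = seed)
  track_dose(b$sensor, list(participant_id = p$id, threshold_c = threshold),
             start_clock_time = clock_time)
}
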