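#' The 15-day home-training day pattern
#'
#' The observed 15-day home recording: morning/afternoon sessions on days 1,
#' 2, 5, 7, 11, 12 and 15, evening sessions on days 3, 6, 8 and 9, and no
#' training on days 4, 10, 13 and 14 (11 trained days in all).
#'
#' @return Character vector of length 15 with values `"afternoon"`,
#'   `"evening"`, `"skip"`.
#' @export
home_trace_days <- function() {
  w <- rep("skip", 15)
  w[c(1, 2, 5, 7, 11, 12, 15)] <- "afternoon"
  w[c(3, 6, 8, 9)] <- "evening"
  w
}

# The home-program participant: dose prescribed as a round 10 degC, work-rate
# scale such that the 30-min calibration bout reaches ~10.0 degC (top of the
# observed 7.1-10.0 degC dose range).
home_participant <- function(config = study_defaults()) {
  unit_dose <- 8.1
  participant("HOME", age = 45, hr_rest = 62,
              power_scale = 10 / unit_dose,
              fatigue_onset_ref = config$fatigue$onset_ref,
              fatigue_slope = config$fatigue$slope,
              fatigue_decay_rate = config$fatigue$decay_rate,
              evening_factor = config$fatigue$evening_factor,
              day_to_day_cv = config$cohort$day_to_day_cv,
              hr_ref = config$fatigue$hr_ref)
}

#' Generate the seeded study dataset
#'
#' Writes the synthetic dataset the analyses run on: a 7-participant cohort
#' (one 30-minute moderate calibration bout each, low-sensitivity sensor CSV
#' + HR CSV + metadata), and one single-participant 8-week home program of
#' dose-taking bouts (per-bout CSVs, a continuous multi-day trace, and the
#' dose-event table). Output is deterministic: identical `seed` and config
#' give byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed.
#' @param weeks Length of the home program in weeks.
#' @param config Configuration list.
#' @return Invisibly, a list with the cohort, prescriptions, program and
#'   dose events.
#' @export
generate_fixtures <- function(dir, seed = study_defaults()$seeds$master,
                              weeks = 8, config = study_defaults()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dev_low <- device_params("low",
                           gain_alpha = config$device$low$gain_alpha,
                           cooling_lambda = config$device$low$cooling_lambda,
                           noise_sd = config$device$low$noise_sd)

  cohort <- make_cohort(config$cohort$n_participants, config$cohort$variability_cv,
                        seed = derive_seed(seed, "cohort"), config = config)
  bouts <- list()
  rxs <- list()
  for (p in cohort) {
    rx <- calibrate_participant(p, dev_low, date = "2015-03-02",
                                seed = derive_seed(seed, p$id, "calibration"),
                                config = config)
    b <- attr(rx, "bout")
    attr(rx, "bout") <- NULL
    rxs[[p$id]] <- rx
    bouts[[p$id]] <- b
    write_sensor_csv(b$sensor, file.path(dir, sprintf("%s_calibration_sensor.csv", p$id)))
    write_hr_csv(b$hr, file.path(dir, sprintf("%s_calibration_hr.csv", p$id)))
  }
  write_bout_metadata(bouts, file.path(dir, "calibration_bouts.jsonl"))

  home <- home_participant(config)
  sched <- program_schedule(weeks = weeks, seed = derive_seed(seed, "home-program"))
  prog <- simulate_program(home, sched, dose_regimen(10, config = config),
                           dev_low, config = config)
  rx_home <- structure(list(participant_id = home$id, threshold_c = 10,
                            calibrated_from = NA, calibrated_date = NA),
                       class = "dose_prescription")
  events <- program_dose_events(prog, rx_home)
  for (i in seq_along(prog$bouts)) {
    write_sensor_csv(prog$bouts[[i]]$sensor,
                     file.path(dir, sprintf("home_bout_%02d_sensor.csv", i)))
  }
  utils::write.csv(data.frame(minute = prog$continuous$minute,
                              delta_t_c = round(prog$continuous$delta_t_c, 3)),
                   file.path(dir, "home_continuous_trace.csv"),
                   row.names = FALSE, quote = FALSE)
  write_dose_events_csv(events, file.path(dir, "home_dose_events.csv"))

  invisible(list(cohort = cohort, prescriptions = rxs, program = prog,
                 events = events))
}
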