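#' Reproduce the study's headline analyses on a synthetic cohort
#'
#' Runs the full desk-scale study under one master seed: dose calibration for
#' a seeded cohort of participants (30-minute fatigue-free moderate bouts,
#' low sensitivity), high-sensitivity plateau measurement for the same
#' cohort, a one-week home-training program per participant (mean dose-taking
#' time and compliance), the 20-afternoon / 20-evening diurnal comparison for
#' the home-program participant, the 15-day home-trace notification count,
#' and the duration-proportional dose fractions.
#'
#' @param seed Master seed; every random draw derives from it.
#' @param config Configuration list, by default [study_defaults()].
#' @return A list of class `study_results`:
#' \describe{
#'   \item{doses}{per-participant calibrated thresholds (degC) and their mean.}
#'   \item{plateaus}{per-participant high-sensitivity plateau medians (degC).}
#'   \item{dose_taking}{completed home-week dose events, their `t_full` values
#'     and mean duration (min).}
#'   \item{compliance}{notification-days/week summary across the home week.}
#'   \item{diurnal}{the [diurnal_compare()] report for 20 afternoon and 20
#'     evening dose-taking bouts of the home-program participant.}
#'   \item{notifications_15day}{notification count over the 15-day pattern.}
#'   \item{dose_fractions}{dose fractions for 15/30/60-minute bouts.}
#' }
#' @export
#' @examples
#' \donttest{
#' res <- run_study(seed = 1)
#' res$doses$mean
#' }
run_study <- function(seed = study_defaults()$seeds$master,
                      config = study_defaults()) {
  dev_low <- device_params("low",
                           gain_alpha = config$device$low$gain_alpha,
                           cooling_lambda = config$device$low$cooling_lambda,
                           noise_sd = config$device$low$noise_sd)
  dev_high <- device_params("high",
                            gain_alpha = config$device$high$gain_alpha,
                            cooling_lambda = config$device$high$cooling_lambda,
                            noise_sd = config$device$high$noise_sd)

  # --- personalized doses: 30-min fatigue-free MICT at HR 100, low mode ---
  cohort <- make_cohort(config$cohort$n_participants,
                        config$cohort$variability_cv,
                        seed = derive_seed(seed, "cohort"), config = config)
  rxs <- lapply(cohort, function(p) {
    calibrate_participant(p, dev_low,
                          seed = derive_seed(seed, p$id, "calibration"),
                          config = config)
  })
  thresholds <- vapply(rxs, `[[`, numeric(1), "threshold_c")

  # --- high-sensitivity plateaus for the same cohort ---
  plateaus <- vapply(cohort, function(p) {
    b <- simulate_bout(p, regimen("hold_hr", 100, duration = 30), dev_high,
                       date = "2015-03-09", clock_time = "14:00",
                       seed = derive_seed(seed, p$id, "plateau"),
                       config = config)
    segment_phases(b$sensor)$plateau_median
  }, numeric(1))

  # --- one home week per participant (excluding the home-program subject):
  #     dose-taking durations and compliance ---
  week_cohort <- cohort[seq_len(min(6, length(cohort)))]
  week_events <- list()
  for (i in seq_along(week_cohort)) {
    p <- week_cohort[[i]]
    sched <- program_schedule(weeks = 1,
                              adherence_prob = config$schedule$adherence_prob,
                              seed = derive_seed(seed, p$id, "home-week"))
    prog <- simulate_program(p, sched, dose_regimen(thresholds[i], config = config),
                             dev_low, start_date = "2015-07-06", config = config)
    week_events <- c(week_events, program_dose_events(prog, rxs[[i]]))
  }
  week_tab <- dose_events_table(week_events)
  t_fulls <- week_tab$t_full[week_tab$completed]
  compliance <- compliance_summary(week_events, weeks = 1)

  # --- diurnal comparison: 20 afternoon + 20 evening dose-taking bouts of
  #     the home-program participant (10 degC prescription) ---
  home <- home_participant(config)
  rx_home <- list(participant_id = home$id, threshold_c = 10)
  diurnal_events <- list()
  windows <- config$schedule
  for (g in c("afternoon", "evening")) {
    lim <- clock_to_minutes(if (g == "afternoon") windows$afternoon_window
                            else windows$evening_window)
    for (k in 1:20) {
      bseed <- derive_seed(seed, "diurnal", g, k)
      clock <- with_seed(bseed, minutes_to_clock(stats::runif(1, lim[1], lim[2])))
      b <- simulate_bout(home, dose_regimen(10, config = config), dev_low,
                         date = as.Date("2015-08-03") + k, clock_time = clock,
                         seed = derive_seed(bseed, "bout"), config = config)
      diurnal_events[[length(diurnal_events) + 1]] <-
        track_dose(b$sensor, rx_home, start_clock_time = clock, date = b$date)
    }
  }
  diurnal <- diurnal_compare(diurnal_events,
                             cutoff = config$fatigue$evening_cutoff)

  # --- 15-day home trace with its 4 skip days ---
  sched15 <- program_schedule(n_days = 15, day_windows = home_trace_days(),
                              seed = derive_seed(seed, "home-15day"))
  prog15 <- simulate_program(home, sched15, dose_regimen(10, config = config),
                             dev_low, start_date = "2015-09-01", config = config)
  ev15 <- program_dose_events(prog15, rx_home)
  notifications <- sum(vapply(ev15, `[[`, logical(1), "completed"))

  structure(list(
    doses = list(thresholds = thresholds, mean = mean(thresholds),
                 sd = stats::sd(thresholds)),
    plateaus = list(values = plateaus, mean = mean(plateaus),
                    sd = stats::sd(plateaus)),
    dose_taking = list(events = week_tab, t_full = t_fulls,
                       mean = mean(t_fulls), sd = stats::sd(t_fulls),
                       n = length(t_fulls)),
    compliance = compliance,
    diurnal = diurnal,
    notifications_15day = notifications,
    dose_fractions = dose_fraction(c(15, 30, 60)),
    seed = seed
  ), class = "study_results")
}

#' @export
print.study_results <- function(x, ...) {
  cat("Synthetic study reproduction (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  personalized dose: mean %.1f (SD %.1f) degC, N=%d\n",
              x$doses$mean, x$doses$sd, length(x$doses$thresholds)))
  cat(sprintf("  high-sensitivity plateau: mean %.1f (SD %.1f) degC\n",
              x$plateaus$mean, x$plateaus$sd))
  cat(sprintf("  dose-taking time: mean %.1f (SD %.1f) min, n=%d\n",
              x$dose_taking$mean, x$dose_taking$sd, x$dose_taking$n))
  cat(sprintf("  compliance: %.1f (SD %.1f) notification-days/week, N=%d\n",
              x$compliance$mean, x$compliance$sd,
              length(x$compliance$per_participant)))
  cat(sprintf("  15-day home trace: %d notifications\n", x$notifications_15day))
  cat("\n")
  print(x$diurnal)
  invisible(x)
}
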