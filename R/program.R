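#' Multi-week home-training schedule
#'
#' Describes a home-training program: how many days, which days are trained,
#' and the clock-time window of each session. Either supply `day_windows`
#' explicitly (one of `"afternoon"`, `"evening"`, `"skip"` per day, as in the
#' observed 15-day home trace) or let trained days be drawn with probability
#' `adherence_prob` and assigned to the afternoon window with probability
#' `p_afternoon`.
#'
#' @param weeks Number of weeks (used when `n_days` is not given).
#' @param n_days Number of days; defaults to `7 * weeks`.
#' @param adherence_prob Probability that a scheduled day is trained (0-1).
#' @param p_afternoon Probability a trained day falls in the afternoon window.
#' @param afternoon_window,evening_window `c("HH:MM", "HH:MM")` clock-time
#'   windows that session start times are drawn uniformly from.
#' @param day_windows Optional explicit character vector of length `n_days`.
#' @param seed Optional integer seed for day sampling.
#' @return An object of class `program_schedule`.
#' @export
program_schedule <- function(weeks = 1, n_days = NULL, adherence_prob = NULL,
                             p_afternoon = NULL, afternoon_window = NULL,
                             evening_window = NULL, day_windows = NULL,
                             seed = NULL) {
  sch <- study_defaults()$schedule
  n_days <- as.integer(n_days %||% (7 * weeks))
  if (n_days < 1) stop("schedule must cover at least one day", call. = FALSE)
  adherence_prob <- adherence_prob %||% sch$adherence_prob
  if (adherence_prob < 0 || adherence_prob > 1) {
    stop("adherence_prob must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(day_windows)) {
    day_windows <- match.arg(day_windows, c("afternoon", "evening", "skip"),
                             several.ok = TRUE)
    if (length(day_windows) != n_days) {
      stop("day_windows must have length n_days", call. = FALSE)
    }
  }
  structure(list(
    n_days = n_days,
    weeks = n_days / 7,
    adherence_prob = adherence_prob,
    p_afternoon = p_afternoon %||% sch$p_afternoon,
    afternoon_window = afternoon_window %||% sch$afternoon_window,
    evening_window = evening_window %||% sch$evening_window,
    day_windows = day_windows,
    seed = seed
  ), class = "program_schedule")
}

#' Simulate a multi-week home-training program
#'
#' Runs one bout per trained day of the schedule (at a clock time drawn from
#' the day's window) and assembles the continuous multi-day device trace:
#' bouts are concatenated on an absolute minute grid with exponential cooling
#' toward baseline between sessions, the way a permanently installed device
#' records. Per-bout seeds are derived by stable hashing of (participant,
#' date), so programs are reproducible under `sched$seed` while bouts remain
#' mutually independent.
#'
#' @param p A [participant()].
#' @param sched A [program_schedule()].
#' @param r The [regimen()] used on trained days.
#' @param device A [device_params()] object.
#' @param start_date Date of day 1.
#' @param config Configuration list.
#' @return An object of class `training_program`: `bouts` (list of
#'   [simulate_bout()] results), `days` (data frame with one row per day),
#'   and `continuous` (data frame `minute`/`delta_t_c` over the whole
#'   period, minutes counted from midnight of day 1).
#' @export
simulate_program <- function(p, sched, r, device, start_date = "2015-06-01",
                             config = study_defaults()) {
  stopifnot(inherits(p, "participant"), inherits(sched, "program_schedule"),
            inherits(r, "regimen"), inherits(device, "device_params"))
  master <- sched$seed %||% config$seeds$master
  start_date <- as.Date(start_date)

  windows <- sched$day_windows %||% with_seed(
    derive_seed(master, p$id, "schedule"), {
      trained <- stats::runif(sched$n_days) < sched$adherence_prob
      ifelse(trained,
             ifelse(stats::runif(sched$n_days) < sched$p_afternoon,
                    "afternoon", "evening"),
             "skip")
    })

  bouts <- list()
  days <- data.frame(day = seq_len(sched$n_days),
                     date = start_date + seq_len(sched$n_days) - 1,
                     window = windows, start_time = NA_character_,
                     stringsAsFactors = FALSE)
  for (d in seq_len(sched$n_days)) {
    if (windows[d] == "skip") next
    w <- if (windows[d] == "afternoon") sched$afternoon_window else sched$evening_window
    bout_seed <- derive_seed(master, p$id, format(days$date[d]))
    clock <- with_seed(bout_seed, {
      lim <- clock_to_minutes(w)
      minutes_to_clock(stats::runif(1, lim[1], lim[2]))
    })
    bouts[[length(bouts) + 1]] <- simulate_bout(
      p, r, device, date = days$date[d], clock_time = clock,
      seed = derive_seed(bout_seed, "bout"), config = config)
    days$start_time[d] <- clock
  }

  structure(list(
    participant_id = p$id,
    bouts = bouts,
    days = days,
    continuous = build_continuous_trace(bouts, days, device)
  ), class = "training_program")
}

# Concatenate bout traces on an absolute minute grid (minute 0 = midnight of
# day 1) with exponential cooling at the device rate between sessions.
build_continuous_trace <- function(bouts, days, device) {
  total <- nrow(days) * 1440L
  minute <- 0:(total - 1)
  delta <- numeric(total)
  level <- 0
  last_end <- 0L
  for (b in bouts) {
    day_idx <- which(days$date == b$date)[1]
    start <- (day_idx - 1L) * 1440L + as.integer(clock_to_minutes(b$start_time))
    idx_gap <- seq.int(last_end, start - 1L)
    delta[idx_gap + 1L] <- level * exp(-device$cooling_lambda * (idx_gap - last_end))
    level <- level * exp(-device$cooling_lambda * (start - last_end))
    # session rides on the residual warmth of previous sessions
    nb <- nrow(b$sensor)
    idx_bout <- start + seq_len(nb) - 1L
    resid <- level * exp(-device$cooling_lambda * (seq_len(nb) - 1))
    keep <- idx_bout < total
    delta[idx_bout[keep] + 1L] <- b$sensor$delta_t_c[keep] + resid[keep]
    last_end <- min(start + nb, total)
    level <- delta[last_end]
    if (is.na(level)) level <- 0
  }
  if (last_end < total) {
    idx_gap <- seq.int(last_end, total - 1L)
    delta[idx_gap + 1L] <- level * exp(-device$cooling_lambda * (idx_gap - last_end))
  }
  data.frame(minute = minute, delta_t_c = delta)
}

#' @export
print.training_program <- function(x, ...) {
  cat(sprintf("<training_program> %s: %d days, %d bouts (%d afternoon / %d evening)\n",
              x$participant_id, nrow(x$days), length(x$bouts),
              sum(x$days$window == "afternoon"), sum(x$days$window == "evening")))
  invisible(x)
}

#' Track the dose over every bout of a program
#'
#' Applies [track_dose()] to each bout of a [simulate_program()] result,
#' returning one [dose_event] per bout (a logged notification event when the
#' threshold is reached).
#'
#' @param program A `training_program`.
#' @param rx A [dose_prescription][calibrate_dose()].
#' @return A list of `dose_event` objects.
#' @export
program_dose_events <- function(program, rx) {
  stopifnot(inherits(program, "training_program"))
  lapply(program$bouts, function(b) {
    track_dose(b$sensor, rx, start_clock_time = b$start_time, date = b$date)
  })
}
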