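#' Calibrate a personalized exercise dose
#'
#' The personalized daily dose of moderate-intensity continuous training
#' (MICT) is the temperature rise the participant reaches in a 30-minute
#' fatigue-free moderate bout recorded in low-sensitivity mode. Calibration
#' is refused for bouts in which fatigue was detected (a dose must reflect
#' fatigue-free performance), for bouts shorter than 30 minutes, and for
#' high-sensitivity traces (whose plateaus are not duration-proportional).
#'
#' @param bout A calibration [simulate_bout()] result (or equivalent list)
#'   with a low-sensitivity sensor trace of >= 30 minutes.
#' @param assessment The bout's [detect_fatigue()] result.
#' @param round_to Rounding of the threshold in degC (default 0.1; the study
#'   prescription rounded one participant's dose to a whole 10 degC, which
#'   callers can reproduce with `round_to = 1`).
#' @return An object of class `dose_prescription`: `participant_id`,
#'   `threshold_c`, `calibrated_from` (date), `calibrated_date`.
#' @export
calibrate_dose <- function(bout, assessment, round_to = 0.1) {
  stopifnot(inherits(assessment, "fatigue_assessment"))
  if (!assessment$fatigue_free) {
    stop("calibration refused: the calibration bout must be fatigue-free",
         call. = FALSE)
  }
  if (attr(bout$sensor, "mode") != "low") {
    stop("calibration requires a low-sensitivity trace", call. = FALSE)
  }
  duration <- bout$duration %||% bout$sensor$minute[nrow(bout$sensor)]
  if (duration < 30) {
    stop("calibration bout must last at least 30 minutes", call. = FALSE)
  }
  at30 <- bout$sensor$delta_t_c[bout$sensor$minute == 30]
  threshold <- round(at30 / round_to) * round_to
  if (threshold <= 0) {
    stop("calibration refused: no temperature rise after 30 minutes",
         call. = FALSE)
  }
  structure(list(
    participant_id = bout$participant_id %||% NA_character_,
    threshold_c = threshold,
    calibrated_from = bout$date %||% NA,
    calibrated_date = bout$date %||% NA
  ), class = "dose_prescription")
}

#' Calibrate a participant's dose by supervised bout, repeating if needed
#'
#' Runs the calibration protocol end to end: simulate a 30-minute moderate
#' (HR 100) low-sensitivity bout, assess it with [detect_fatigue()], and
#' calibrate the dose from it. If the bout is not fatigue-free the
#' calibration is repeated on the next day (up to `max_tries` attempts), as a
#' supervised protocol would; an error is raised only if every attempt shows
#' fatigue.
#'
#' @param p A [participant()].
#' @param device A low-sensitivity [device_params()] object.
#' @param date First calibration date.
#' @param seed Integer seed; attempt `k` derives its bout seed from
#'   `seed + k - 1`.
#' @param max_tries Maximum calibration attempts.
#' @param config Configuration list.
#' @return A `dose_prescription` (see [calibrate_dose()]).
#' @export
calibrate_participant <- function(p, device, date = "2015-03-02", seed = 1,
                                  max_tries = 3, config = study_defaults()) {
  last_err <- NULL
  for (k in seq_len(max_tries)) {
    b <- simulate_bout(p, regimen("hold_hr", 100, duration = 30), device,
                       date = as.Date(date) + k - 1, clock_time = "14:00",
                       seed = seed + k - 1, config = config)
    a <- detect_fatigue(b, device, criteria = config$analysis)
    rx <- tryCatch(calibrate_dose(b, a), error = function(e) e)
    if (!inherits(rx, "error")) {
      attr(rx, "bout") <- b
      return(rx)
    }
    last_err <- rx
  }
  stop("calibration failed after ", max_tries, " attempts: ",
       conditionMessage(last_err), call. = FALSE)
}

#' @export
print.dose_prescription <- function(x, ...) {
  cat(sprintf("<dose_prescription> %s: %.1f degC (30-min fatigue-free MICT dose)\n",
              x$participant_id, x$threshold_c))
  invisible(x)
}

#' Track dose-taking on a session trace
#'
#' Finds the times at which a baseline-zeroed low-sensitivity trace reaches
#' half and all of the prescribed dose, with linear interpolation between the
#' 1-minute samples (reported to 0.1 min, avoiding +-1 min quantization).
#' Reaching the full dose produces exactly one logged notification event per
#' bout, timestamped `start + t_full`. If the threshold is never reached the
#' event is returned with `completed = FALSE`.
#'
#' @param trace A baseline-zeroed [sensor_trace()] (`delta_t[1] <= 0.5`).
#' @param rx A [calibrate_dose()] prescription (or any list with
#'   `threshold_c` and `participant_id`).
#' @param start_clock_time Session start as `"HH:MM"`.
#' @param date Session date.
#' @return An object of class `dose_event`: `participant_id`, `date`,
#'   `start_clock_time`, `threshold_c`, `t_half`, `t_full` (minutes, 0.1-min
#'   resolution; NA when not reached), `notified_at` (`"HH:MM"` or NA) and
#'   `completed`.
#' @export
track_dose <- function(trace, rx, start_clock_time = "14:00", date = NA) {
  stopifnot(all(c("minute", "delta_t_c") %in% names(trace)))
  if (trace$delta_t_c[1] > 0.5) {
    stop("trace is not baseline-zeroed (delta_t[0] > 0.5 degC)", call. = FALSE)
  }
  threshold <- rx$threshold_c
  stopifnot(is.numeric(threshold), threshold > 0)
  t_half <- crossing_time(trace$minute, trace$delta_t_c, threshold / 2)
  t_full <- crossing_time(trace$minute, trace$delta_t_c, threshold)
  completed <- !is.na(t_full)
  notified_at <- if (completed) {
    minutes_to_clock(clock_to_minutes(start_clock_time) + t_full)
  } else NA_character_
  structure(list(
    participant_id = rx$participant_id %||% NA_character_,
    date = if (inherits(date, "Date")) date else suppressWarnings(as.Date(date)),
    start_clock_time = start_clock_time,
    threshold_c = threshold,
    t_half = t_half,
    t_full = t_full,
    notified_at = notified_at,
    completed = completed
  ), class = "dose_event")
}

# First crossing of `level`, linearly interpolated, rounded to 0.1 min.
crossing_time <- function(minute, delta, level) {
  i <- which(delta >= level)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(0)
  t <- minute[i - 1] + (level - delta[i - 1]) / (delta[i] - delta[i - 1]) *
    (minute[i] - minute[i - 1])
  round(t, 1)
}

#' @export
print.dose_event <- function(x, ...) {
  if (x$completed) {
    cat(sprintf("<dose_event> %s %s %s: %.1f degC dose taken in %.1f min (half in %.1f), notified %s\n",
                x$participant_id, format(x$date), x$start_clock_time,
                x$threshold_c, x$t_full, x$t_half, x$notified_at))
  } else {
    cat(sprintf("<dose_event> %s %s %s: %.1f degC dose NOT completed\n",
                x$participant_id, format(x$date), x$start_clock_time,
                x$threshold_c))
  }
  invisible(x)
}

#' Dose fraction of a bout duration
#'
#' For fatigue-free bouts at a reproducible work rate the low-sensitivity
#' temperature rise is proportional to duration, so the exercise volume of a
#' bout is its duration relative to the 30-minute reference dose: 15, 30 and
#' 60 minutes correspond to 0.5, 1.0 and 2.0 daily doses.
#'
#' @param bout_duration Bout duration in minutes (> 0).
#' @param rx_reference_duration Reference duration in minutes (default 30).
#' @return The dose fraction (dimensionless).
#' @export
#' @examples
#' dose_fraction(c(15, 30, 60))
dose_fraction <- function(bout_duration, rx_reference_duration = 30) {
  if (any(bout_duration <= 0) || rx_reference_duration <= 0) {
    stop("durations must be > 0", call. = FALSE)
  }
  bout_duration / rx_reference_duration
}

#' Split a continuous multi-day trace into zeroed sessions
#'
#' A permanently installed device records one continuous trace across days.
#' Sessions are separated by quiet gaps -- runs of at least `min_gap` minutes
#' in which the smoothed trace never rises faster than `slope_tol` -- and
#' each session is re-zeroed to its own starting value, mirroring the
#' protocol of zeroing the reading before every session.
#'
#' @param continuous Data frame with columns `minute` and `delta_t_c`.
#' @param mode Sensitivity mode of the recording.
#' @param min_gap Minimum quiet-gap length in minutes.
#' @param slope_tol Rise-rate threshold in degC/min separating activity from
#'   idle cooling.
#' @return A list of baseline-zeroed [sensor_trace()] objects with a
#'   `start_minute` attribute each.
#' @export
split_sessions <- function(continuous, mode = "low", min_gap = 60,
                           slope_tol = 0.05) {
  stopifnot(all(c("minute", "delta_t_c") %in% names(continuous)))
  s <- moving_slope(continuous$minute, continuous$delta_t_c, 5)
  active <- s > slope_tol
  # close holes shorter than min_gap so within-session pauses do not split
  r <- rle(active)
  idx_end <- cumsum(r$lengths)
  for (j in seq_along(r$lengths)) {
    if (!r$values[j] && r$lengths[j] < min_gap && j > 1 && j < length(r$lengths)) {
      active[(idx_end[j] - r$lengths[j] + 1):idx_end[j]] <- TRUE
    }
  }
  r <- rle(active)
  idx_end <- cumsum(r$lengths)
  sessions <- list()
  for (j in seq_along(r$lengths)) {
    if (!r$values[j]) next
    from <- idx_end[j] - r$lengths[j] + 1
    to <- idx_end[j]
    if (to - from < 5) next
    d <- continuous$delta_t_c[from:to]
    sessions[[length(sessions) + 1]] <- structure(
      sensor_trace(seq_len(to - from + 1) - 1, d - d[1], mode = mode),
      start_minute = continuous$minute[from])
  }
  sessions
}
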