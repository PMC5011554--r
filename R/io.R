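#' Read and write sensor CSV files
#'
#' Session traces are exchanged as CSV with header `minute,delta_t_c`, one
#' file per session; the sensitivity mode lives in session metadata, not in
#' the CSV. The reader validates the minute grid (gaps of at most 2 minutes
#' are filled by linear interpolation with a warning; larger gaps and
#' non-monotone minutes are errors naming the offending row), and a constant
#' positive baseline offset of at most 0.5 degC is subtracted with a warning
#' (sessions are zeroed before training; small leftovers are tolerated).
#' Write-then-read round-trips are identities at 3-decimal precision.
#'
#' @param path File path.
#' @param mode Sensitivity mode to attach to the trace.
#' @return `read_sensor_csv()` returns a [sensor_trace()];
#'   `write_sensor_csv()` returns `path` invisibly.
#' @export
read_sensor_csv <- function(path, mode = c("low", "high")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("minute", "delta_t_c") %in% names(df))) {
    stop("sensor CSV must have columns minute,delta_t_c", call. = FALSE)
  }
  if (any(diff(df$minute) <= 0)) {
    row <- which(diff(df$minute) <= 0)[1] + 1
    stop("non-monotone minutes at row ", row, call. = FALSE)
  }
  gaps <- diff(df$minute)
  if (any(gaps > 2)) {
    row <- which(gaps > 2)[1] + 1
    stop("gap of ", max(gaps), " minutes at row ", row,
         " exceeds the 2-minute limit", call. = FALSE)
  }
  if (any(gaps > 1)) {
    warning("gap(s) in minute grid; missing samples linearly interpolated",
            call. = FALSE)
    full <- seq(df$minute[1], df$minute[nrow(df)])
    df <- data.frame(minute = full,
                     delta_t_c = stats::approx(df$minute, df$delta_t_c, full)$y)
  }
  if (df$minute[1] != 0) stop("minutes must start at 0", call. = FALSE)
  if (df$delta_t_c[1] != 0 && abs(df$delta_t_c[1]) <= 0.5) {
    warning(sprintf("baseline offset of %.3f degC subtracted", df$delta_t_c[1]),
            call. = FALSE)
    df$delta_t_c <- df$delta_t_c - df$delta_t_c[1]
  } else if (df$delta_t_c[1] != 0) {
    stop("trace baseline offset exceeds 0.5 degC; re-zero the session",
         call. = FALSE)
  }
  sensor_trace(df$minute, df$delta_t_c, mode = mode)
}

#' @param trace A [sensor_trace()].
#' @rdname read_sensor_csv
#' @export
write_sensor_csv <- function(trace, path) {
  stopifnot(inherits(trace, "sensor_trace"))
  df <- data.frame(minute = trace$minute,
                   delta_t_c = round(trace$delta_t_c, 3))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write heart-rate CSV files
#'
#' Heart-rate exports are minute-averaged to the session grid with header
#' `minute,bpm`. Rows with physiologically impossible values (below 30 or
#' above 230 BPM) are rejected with an error naming the row. The percent of
#' the age-predicted maximum (HRmax = 220 - age) is annotated per sample.
#'
#' @param path File path.
#' @param participant_age Age in years (used for HRmax).
#' @return `read_hr_csv()` returns an [hr_trace()]; `write_hr_csv()` returns
#'   `path` invisibly.
#' @export
read_hr_csv <- function(path, participant_age) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(is.numeric(participant_age), participant_age > 0)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("minute", "bpm") %in% names(df))) {
    stop("HR CSV must have columns minute,bpm", call. = FALSE)
  }
  bad <- which(df$bpm < 30 | df$bpm > 230)
  if (length(bad) > 0) {
    stop("implausible heart rate (", df$bpm[bad[1]], " BPM) at row ", bad[1],
         call. = FALSE)
  }
  if (any(diff(df$minute) <= 0)) {
    row <- which(diff(df$minute) <= 0)[1] + 1
    stop("non-monotone minutes at row ", row, call. = FALSE)
  }
  hr_trace(df$minute, df$bpm, hr_max = 220 - participant_age)
}

#' @param trace An [hr_trace()].
#' @rdname read_hr_csv
#' @export
write_hr_csv <- function(trace, path) {
  stopifnot(inherits(trace, "hr_trace"))
  utils::write.csv(data.frame(minute = trace$minute, bpm = round(trace$bpm)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write dose events to CSV
#'
#' One row per dose event:
#' `participant_id,date,start_time,threshold_c,t_half_min,t_full_min,notified_at,completed`.
#'
#' @param events List of `dose_event`s or a [dose_events_table()] frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_dose_events_csv <- function(events, path) {
  tab <- if (is.data.frame(events)) events else dose_events_table(events)
  out <- data.frame(participant_id = tab$participant_id, date = tab$date,
                    start_time = tab$start_clock_time,
                    threshold_c = tab$threshold_c,
                    t_half_min = tab$t_half, t_full_min = tab$t_full,
                    notified_at = tab$notified_at, completed = tab$completed)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write bout session metadata as JSON lines
#'
#' One JSON record per bout: participant, ISO date, start time, sensitivity
#' mode, regimen fields and reported RPE.
#'
#' @param bouts List of [simulate_bout()] results.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_bout_metadata <- function(bouts, path) {
  lines <- vapply(bouts, function(b) {
    jsonlite::toJSON(list(
      participant_id = b$participant_id,
      date = format(b$date),
      start_time = b$start_time,
      mode = attr(b$sensor, "mode"),
      control = b$regimen$control,
      target = b$regimen$target,
      stop_rule = b$regimen$stop_rule,
      dose_threshold = b$regimen$dose_threshold,
      duration = b$duration,
      rpe = b$rpe_reported
    ), auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
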