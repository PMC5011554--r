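#' Minute-sampled device temperature trace
#'
#' A `sensor_trace` holds the exercise-induced temperature rise of the
#' training-device resistance unit (delta-t, degC above the session-start
#' baseline) sampled on a uniform 1-minute grid, together with the sensor
#' sensitivity mode. Traces are baseline-zeroed: `delta_t[1]` must be 0 and
#' small negative noise excursions (>= -0.5 degC) are tolerated elsewhere.
#'
#' @param times Minutes from session start; strictly increasing with unit
#'   spacing, starting at 0.
#' @param delta_t Temperature rise in degC, finite, `delta_t[1] == 0`.
#' @param mode Sensitivity mode, `"high"` or `"low"`.
#' @return An object of class `sensor_trace`: a data frame with columns
#'   `minute` and `delta_t_c` plus a `mode` attribute.
#' @seealso [simulate_temperature()], [read_sensor_csv()]
#' @export
sensor_trace <- function(times, delta_t, mode = c("high", "low")) {
  mode <- match.arg(mode)
  times <- as.numeric(times)
  delta_t <- as.numeric(delta_t)
  if (length(times) != length(delta_t)) {
    stop("times and delta_t must have equal length", call. = FALSE)
  }
  check_minute_grid(times)
  if (any(!is.finite(delta_t))) stop("delta_t must be finite", call. = FALSE)
  if (delta_t[1] != 0) stop("trace is not baseline-zeroed: delta_t[1] != 0", call. = FALSE)
  if (any(delta_t < -0.5)) {
    stop("delta_t below -0.5 degC: not a baseline-zeroed trace", call. = FALSE)
  }
  out <- data.frame(minute = times, delta_t_c = delta_t)
  attr(out, "mode") <- mode
  class(out) <- c("sensor_trace", "data.frame")
  out
}

check_minute_grid <- function(times) {
  if (length(times) < 1 || times[1] != 0) {
    stop("times must start at 0", call. = FALSE)
  }
  if (length(times) > 1 && any(abs(diff(times) - 1) > 1e-8)) {
    stop("times must be a uniform 1-minute grid", call. = FALSE)
  }
  invisible(times)
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat(sprintf("<sensor_trace> %s-sensitivity, %d min, peak %.1f degC\n",
              attr(x, "mode"), nrow(x) - 1, max(x$delta_t_c)))
  invisible(x)
}

#' @export
plot.sensor_trace <- function(x, ...) {
  graphics::plot(x$minute, x$delta_t_c, type = "l", xlab = "minute",
                 ylab = expression(Delta * t * degree * " (C)"), ...)
  invisible(x)
}

#' Latent work-rate trace
#'
#' A `power_trace` is the latent leg work output (LWO) driving the thermal
#' model, in dimensionless work-units per minute where 1.0 is the
#' mean-participant moderate-intensity work rate.
#'
#' @param times Minutes from session start, uniform 1-minute grid from 0.
#' @param power Work-rate in work-units/min; non-negative.
#' @return An object of class `power_trace` (data frame with columns
#'   `minute`, `power`).
#' @export
power_trace <- function(times, power) {
  times <- as.numeric(times)
  power <- as.numeric(power)
  if (length(times) != length(power)) {
    stop("times and power must have equal length", call. = FALSE)
  }
  check_minute_grid(times)
  if (any(!is.finite(power)) || any(power < 0)) {
    stop("power must be finite and non-negative", call. = FALSE)
  }
  out <- data.frame(minute = times, power = power)
  class(out) <- c("power_trace", "data.frame")
  out
}

#' @export
print.power_trace <- function(x, ...) {
  cat(sprintf("<power_trace> %d min, mean %.2f work-units/min\n",
              nrow(x) - 1, mean(x$power)))
  invisible(x)
}

#' Minute-sampled heart-rate trace
#'
#' Heart rate in beats per minute on the session 1-minute grid, annotated with
#' the percentage of the age-predicted maximum (HRmax = 220 - age).
#'
#' @param times Minutes from session start, uniform 1-minute grid from 0.
#' @param bpm Heart rate, 30-230 BPM.
#' @param hr_max Age-predicted maximal heart rate in BPM.
#' @return An object of class `hr_trace` (data frame with columns `minute`,
#'   `bpm`, `pct_hr_max`).
#' @export
hr_trace <- function(times, bpm, hr_max) {
  times <- as.numeric(times)
  bpm <- as.numeric(bpm)
  if (length(times) != length(bpm)) {
    stop("times and bpm must have equal length", call. = FALSE)
  }
  check_minute_grid(times)
  if (any(bpm < 30 | bpm > 230)) {
    stop("bpm outside the plausible 30-230 BPM range", call. = FALSE)
  }
  stopifnot(is.numeric(hr_max), hr_max > 0)
  out <- data.frame(minute = times, bpm = bpm, pct_hr_max = 100 * bpm / hr_max)
  attr(out, "hr_max") <- hr_max
  class(out) <- c("hr_trace", "data.frame")
  out
}

#' @export
print.hr_trace <- function(x, ...) {
  cat(sprintf("<hr_trace> %d min, mean %.0f BPM (%.0f%% HRmax)\n",
              nrow(x) - 1, mean(x$bpm), mean(x$pct_hr_max)))
  invisible(x)
}
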