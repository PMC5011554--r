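#' Training regimen
#'
#' A regimen prescribes how a bout is driven and when it stops. Under
#' `control = "hold_hr"` the participant keeps their heart rate on the target
#' (within the 10-BPM control band) and their work rate is whatever that
#' intensity yields, declining after fatigue onset; under `"hold_power"` the
#' work rate is held constant and the heart rate drifts upward after onset.
#' `stop_rule = "fixed_duration"` runs for `duration` minutes;
#' `"dose_reached"` stops one sample after the temperature rise crosses
#' `dose_threshold`.
#'
#' @param control `"hold_hr"` or `"hold_power"`.
#' @param target Heart-rate target in BPM (`hold_hr`) or work rate in
#'   work-units/min (`hold_power`).
#' @param duration Bout duration in minutes (`fixed_duration`).
#' @param stop_rule `"fixed_duration"` or `"dose_reached"`.
#' @param dose_threshold Temperature-rise threshold in degC (`dose_reached`).
#' @param effort_gain Multiplier on the participant's work rate for this
#'   regimen. Home dose-taking uses the calibrated default (see
#'   [dose_regimen()]); supervised calibration bouts use 1.
#' @return An object of class `regimen`.
#' @export
regimen <- function(control = c("hold_hr", "hold_power"), target,
                    duration = 30, stop_rule = c("fixed_duration", "dose_reached"),
                    dose_threshold = NULL, effort_gain = 1) {
  control <- match.arg(control)
  stop_rule <- match.arg(stop_rule)
  if (stop_rule == "fixed_duration") {
    if (!is.numeric(duration) || duration <= 0) {
      stop("duration must be > 0", call. = FALSE)
    }
  } else {
    if (is.null(dose_threshold) || dose_threshold <= 0) {
      stop("dose_reached requires dose_threshold > 0", call. = FALSE)
    }
  }
  if (effort_gain <= 0) stop("effort_gain must be > 0", call. = FALSE)
  structure(list(control = control, target = target, duration = duration,
                 stop_rule = stop_rule, dose_threshold = dose_threshold,
                 effort_gain = effort_gain),
            class = "regimen")
}

#' Home dose-taking regimen
#'
#' Convenience constructor for the regimen used in home self-control
#' training: hold the moderate heart-rate target and stop once the
#' personalized temperature-rise dose is reached. Home sessions run at the
#' calibrated effort gain above the supervised calibration bout, which
#' anchors afternoon dose-taking times near the observed 27.4 minutes.
#'
#' @param dose_threshold Personalized dose threshold in degC.
#' @param target_hr Heart-rate target in BPM.
#' @param config Configuration list supplying the effort gain.
#' @return A [regimen()].
#' @export
dose_regimen <- function(dose_threshold, target_hr = 100,
                         config = study_defaults()) {
  regimen(control = "hold_hr", target = target_hr, stop_rule = "dose_reached",
          dose_threshold = dose_threshold,
          effort_gain = config$fatigue$home_effort_gain)
}

# Fatigue-onset time (minutes) for a participant at a heart-rate target.
fatigue_onset_minutes <- function(p, target_hr, evening = FALSE) {
  onset <- p$fatigue_onset_ref + p$fatigue_slope * (p$hr_ref - target_hr)
  if (evening) onset <- onset / p$evening_factor
  max(onset, 0.5)
}

# Post-onset linear power-decay rate (fraction of initial power per minute).
# Decay accelerates with intensity: scaled by (rel_power / ref_power)^exp.
fatigue_decay_per_min <- function(p, rel_power, evening = FALSE,
                                  config = study_defaults()) {
  ref <- intensity_map(p$hr_ref)
  d <- p$fatigue_decay_rate * (rel_power / ref)^config$fatigue$decay_intensity_exp
  if (evening) d <- d * p$evening_factor
  d
}

#' Simulate a training bout
#'
#' Generates the paired temperature and heart-rate traces of one training
#' session. Under `hold_hr`, the heart rate is the target plus per-minute
#' `Normal(0, 10)` control noise and the latent work rate starts at
#' `power_scale * intensity_map(target) * effort_gain` (times a per-bout
#' day-to-day multiplier), declining linearly after fatigue onset down to a
#' floor of 20% of its initial value. Under `hold_power` the work rate is
#' constant and the heart rate drifts upward toward HRmax after onset.
#' Sessions starting at or after the evening cutoff (17:00) have their onset
#' divided, and their decay rate multiplied, by the participant's
#' `evening_factor`. Bouts with `stop_rule = "dose_reached"` end one sample
#' after the threshold crossing; if the threshold is not reached within a
#' 120-minute safety cap the bout is flagged `timeout`.
#'
#' @param p A [participant()].
#' @param r A [regimen()].
#' @param device A [device_params()] object.
#' @param date Session date (anything `as.Date()` accepts).
#' @param clock_time Session start as `"HH:MM"`.
#' @param seed Optional integer seed; bouts are bit-reproducible under it.
#' @param cooldown Minutes of post-exercise recording appended with zero work
#'   rate (the recovery phase).
#' @param config Configuration list.
#' @return An object of class `training_bout`: participant id, date, start
#'   time, exercise `duration` (minutes), `sensor` ([sensor_trace()]), `hr`
#'   ([hr_trace()]), the latent `power` trace, planted `fatigue_onset` (NA if
#'   beyond the bout), `evening` and `timeout` flags, and `rpe_reported`.
#' @export
#' @examples
#' p <- participant("P01")
#' b <- simulate_bout(p, regimen("hold_hr", 100, duration = 30),
#'                    device_params("low"), date = "2015-03-02", seed = 1)
#' b
simulate_bout <- function(p, r, device, date, clock_time = "14:00",
                          seed = NULL, cooldown = 0,
                          config = study_defaults()) {
  stopifnot(inherits(p, "participant"), inherits(r, "regimen"),
            inherits(device, "device_params"))
  fat <- config$fatigue
  evening <- clock_to_minutes(clock_time) >= clock_to_minutes(fat$evening_cutoff)
  cap <- 120L
  n <- if (r$stop_rule == "fixed_duration") as.integer(round(r$duration)) else cap

  with_seed(seed, {
    day_mult <- max(stats::rnorm(1, 1, p$day_to_day_cv), 0.3)
    minutes <- seq_len(n) - 1L

    if (r$control == "hold_hr") {
      rel <- intensity_map(r$target)
      p0 <- p$power_scale * rel * r$effort_gain * day_mult
      onset <- fatigue_onset_minutes(p, r$target, evening)
      decay <- fatigue_decay_per_min(p, rel, evening, config)
      frac <- pmax(1 - decay * pmax(minutes - onset, 0), fat$power_floor)
      pw <- p0 * frac
      bpm <- r$target + stats::rnorm(n, 0, fat$hr_noise_sd)
    } else {
      pw <- rep(r$target * day_mult, n)
      rel <- r$target / p$power_scale
      hr_equiv <- inverse_intensity_map(rel)
      onset <- fatigue_onset_minutes(p, hr_equiv, evening)
      drift <- fat$hr_drift_rate * pmax(minutes - onset, 0)
      bpm <- pmin(hr_equiv + drift, p$hr_max) + stats::rnorm(n, 0, fat$hr_noise_sd)
    }
    bpm <- pmin(pmax(round(bpm), 30), 230)

    sensor <- simulate_temperature(power_trace(minutes, pw), device,
                                   noise_sd = device$noise_sd)

    timeout <- FALSE
    if (r$stop_rule == "dose_reached") {
      hit <- which(sensor$delta_t_c >= r$dose_threshold)[1]
      if (is.na(hit)) {
        timeout <- TRUE
      } else {
        keep <- min(hit + 1L, nrow(sensor))  # one sample after the crossing
        sensor <- sensor_trace(sensor$minute[1:keep], sensor$delta_t_c[1:keep],
                               mode = attr(sensor, "mode"))
        n <- keep - 1L
        minutes <- seq_len(n) - 1L
        pw <- pw[1:n]
        bpm <- bpm[1:n]
      }
    }

    duration <- n
    if (cooldown > 0) {
      extra <- as.integer(cooldown)
      pw_full <- c(pw, rep(0, extra))
      sensor <- simulate_temperature(power_trace(seq_along(pw_full) - 1, pw_full),
                                     device, noise_sd = device$noise_sd)
      # HR relaxes exponentially toward rest after cessation
      relax <- p$hr_rest + (bpm[length(bpm)] - p$hr_rest) * exp(-0.3 * seq_len(extra))
      bpm <- c(bpm, pmax(round(relax + stats::rnorm(extra, 0, 2)), 30))
      minutes <- seq_along(pw_full) - 1L
      pw <- pw_full
    }

    hr <- hr_trace(c(minutes, minutes[length(minutes)] + 1L),
                   c(bpm, bpm[length(bpm)]), hr_max = p$hr_max)
    rel_eff <- if (r$control == "hold_hr") rel * r$effort_gain else rel
    rpe <- if (rel_eff < 1.2) 13L else if (rel_eff < 1.7) 14L else 16L

    structure(list(
      participant_id = p$id,
      date = as.Date(date),
      start_time = clock_time,
      duration = duration,
      sensor = sensor,
      hr = hr,
      power = power_trace(minutes, pw),
      fatigue_onset = if (onset < duration) onset else NA_real_,
      evening = evening,
      timeout = timeout,
      regimen = r,
      rpe_reported = rpe
    ), class = "training_bout")
  })
}

#' @export
print.training_bout <- function(x, ...) {
  cat(sprintf("<training_bout> %s %s %s: %d min exercise, %s-sensitivity, peak %.1f degC%s\n",
              x$participant_id, format(x$date), x$start_time, x$duration,
              attr(x$sensor, "mode"), max(x$sensor$delta_t_c),
              if (x$timeout) " [timeout]" else ""))
  invisible(x)
}

#' @export
plot.training_bout <- function(x, ...) {
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(x$sensor$minute, x$sensor$delta_t_c, type = "l", col = "blue",
                 xlab = "minute", ylab = "delta-t (degC)",
                 main = sprintf("%s %s %s", x$participant_id, format(x$date),
                                x$start_time), ...)
  graphics::abline(v = x$duration, lty = 3)
  graphics::par(new = TRUE)
  graphics::plot(x$hr$minute, x$hr$bpm, type = "l", col = "brown",
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("HR (BPM)", side = 4, line = 2.5)
  invisible(x)
}
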