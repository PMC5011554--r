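#' Map a heart-rate target to a relative work rate
#'
#' Piecewise-linear map from the prescribed heart-rate target to the relative
#' work rate of the mean participant, anchored at 100 BPM -> 1.0 (moderate),
#' 120 BPM -> 1.5 and 130 BPM -> 1.8 (vigorous). These anchors reproduce the
#' observed ordering of high-sensitivity plateau levels (~34, ~51, ~57 degC)
#' under the calibrated device model. Extrapolation outside 100-130 BPM
#' continues the adjacent segment, floored at 0.2 work-units/min.
#'
#' @param target_hr Heart-rate target in BPM.
#' @return Relative work rate in work-units/min.
#' @export
intensity_map <- function(target_hr) {
  stopifnot(is.numeric(target_hr))
  pmax(stats::approx(x = c(100, 120, 130), y = c(1.0, 1.5, 1.8),
                     xout = target_hr, rule = 2)$y +
         0.025 * pmin(target_hr - 100, 0) +
         0.03 * pmax(target_hr - 130, 0),
       0.2)
}

# Inverse of intensity_map on its increasing range.
inverse_intensity_map <- function(rel_power) {
  stopifnot(is.numeric(rel_power), all(rel_power > 0))
  ifelse(rel_power <= 1.0, 100 + (rel_power - 1.0) / 0.025,
         ifelse(rel_power <= 1.5, 100 + (rel_power - 1.0) / 0.025,
                ifelse(rel_power <= 1.8, 120 + (rel_power - 1.5) / 0.03,
                       130 + (rel_power - 1.8) / 0.03)))
}

#' Construct a synthetic participant
#'
#' Participants carry the physiological parameters of the bout generator: a
#' work-rate scale (their moderate-intensity work rate relative to the mean
#' participant), an age-predicted maximal heart rate (220 - age), and a
#' fatigue law. Fatigue onset is linear in the heart-rate deficit below the
#' vigorous reference (`onset = fatigue_onset_ref + fatigue_slope * (hr_ref -
#' target)`), after which the work rate decays linearly; evening sessions
#' divide the onset by `evening_factor` and multiply the decay rate by it.
#'
#' @param id Participant label.
#' @param age Age in years.
#' @param hr_rest Resting heart rate in BPM (must be below HRmax).
#' @param power_scale Work-rate multiplier relative to the mean participant
#'   (> 0).
#' @param fatigue_onset_ref Minutes to fatigue onset at the reference HR.
#' @param fatigue_slope Minutes of onset gained per BPM below the reference.
#' @param fatigue_decay_rate Fraction of initial power lost per minute after
#'   onset, at the reference intensity.
#' @param evening_factor Diurnal fatigability multiplier (>= 1).
#' @param day_to_day_cv CV of the per-bout work-rate multiplier.
#' @param hr_ref Reference heart rate (BPM) for the fatigue anchors.
#' @return An object of class `participant`.
#' @export
participant <- function(id, age = 40, hr_rest = 65, power_scale = 1,
                        fatigue_onset_ref = NULL, fatigue_slope = NULL,
                        fatigue_decay_rate = NULL, evening_factor = NULL,
                        day_to_day_cv = NULL, hr_ref = NULL) {
  fat <- study_defaults()$fatigue
  coh <- study_defaults()$cohort
  p <- list(
    id = as.character(id),
    age = age,
    hr_max = 220 - age,
    hr_rest = hr_rest,
    power_scale = power_scale,
    fatigue_onset_ref = fatigue_onset_ref %||% fat$onset_ref,
    fatigue_slope = fatigue_slope %||% fat$slope,
    fatigue_decay_rate = fatigue_decay_rate %||% fat$decay_rate,
    evening_factor = evening_factor %||% fat$evening_factor,
    day_to_day_cv = day_to_day_cv %||% coh$day_to_day_cv,
    hr_ref = hr_ref %||% fat$hr_ref
  )
  if (p$hr_rest >= p$hr_max) stop("hr_rest must be below hr_max", call. = FALSE)
  if (p$power_scale <= 0) stop("power_scale must be > 0", call. = FALSE)
  if (p$fatigue_onset_ref <= 0) stop("fatigue_onset_ref must be > 0", call. = FALSE)
  if (p$evening_factor < 1) stop("evening_factor must be >= 1", call. = FALSE)
  class(p) <- "participant"
  p
}

#' @export
print.participant <- function(x, ...) {
  cat(sprintf("<participant %s> age %d (HRmax %d), power scale %.2f, evening factor %.2f\n",
              x$id, x$age, x$hr_max, x$power_scale, x$evening_factor))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Draws `n` participants with work-rate scales `Normal(1, variability_cv)`
#' truncated above 0.5, emulating the observed between-participant spread of
#' both the high-sensitivity plateau levels and the 30-minute low-sensitivity
#' doses. Ages are drawn uniformly over the study range; all fatigue
#' parameters come from `config`.
#'
#' @param n Number of participants (>= 1).
#' @param variability_cv Coefficient of variation of the work-rate scale.
#' @param seed Optional integer seed; the draw is deterministic under it.
#' @param config A configuration list, by default [study_defaults()].
#' @return A list of [participant()] objects.
#' @export
#' @examples
#' cohort <- make_cohort(7, variability_cv = 0.17, seed = 1)
#' sapply(cohort, function(p) p$power_scale)
make_cohort <- function(n, variability_cv = 0.17, seed = NULL,
                        config = study_defaults()) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  coh <- config$cohort
  with_seed(seed, {
    scales <- stats::rnorm(n, 1, variability_cv)
    while (any(scales <= 0.5)) {
      bad <- scales <= 0.5
      scales[bad] <- stats::rnorm(sum(bad), 1, variability_cv)
    }
    ages <- sample(seq(coh$age_range[1], coh$age_range[2]), n, replace = TRUE)
    rests <- round(stats::rnorm(n, coh$hr_rest_mean, coh$hr_rest_sd))
    lapply(seq_len(n), function(i) {
      participant(
        id = sprintf("P%02d", i), age = ages[i], hr_rest = rests[i],
        power_scale = scales[i],
        fatigue_onset_ref = config$fatigue$onset_ref,
        fatigue_slope = config$fatigue$slope,
        fatigue_decay_rate = config$fatigue$decay_rate,
        evening_factor = config$fatigue$evening_factor,
        day_to_day_cv = coh$day_to_day_cv,
        hr_ref = config$fatigue$hr_ref
      )
    })
  })
}

#' Borg RPE category
#'
#' Bands a Borg 6-20 rating of perceived exertion into the study's three
#' categories: light (< 12), moderate (12-14, boundaries inclusive) or
#' strenuous (> 14). RPE is descriptive metadata only; no computation in the
#' package consumes it.
#'
#' @param score Borg scale score, 6-20.
#' @return `"light"`, `"moderate"` or `"strenuous"`.
#' @export
#' @examples
#' rpe_category(c(11, 12, 14, 15))
rpe_category <- function(score) {
  if (any(!is.finite(score)) || any(score < 6 | score > 20)) {
    stop("Borg RPE score must be within 6-20", call. = FALSE)
  }
  ifelse(score < 12, "light", ifelse(score <= 14, "moderate", "strenuous"))
}
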