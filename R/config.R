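#' Default study configuration
#'
#' Returns the nested list of defaults used across the package: device
#' calibration for the two sensitivity modes, cohort generation, the fatigue
#' law, the home-training schedule, analysis tolerances and seeds. Values are
#' calibrated so that a mean participant (unit work rate) reproduces the
#' study-scale anchors: a 34.2 degC high-sensitivity plateau, an 8.1 degC
#' 30-minute low-sensitivity dose, afternoon dose-taking times near 27.4 min
#' and evening times near 33.8 min.
#'
#' @return A named nested list with sections `device` (one entry per mode),
#'   `cohort`, `fatigue`, `schedule`, `analysis` and `seeds`.
#' @export
#' @examples
#' cfg <- study_defaults()
#' cfg$device$high$gain_alpha
study_defaults <- function() {
  list(
    device = list(
      high = list(mode = "high", gain_alpha = 13.68, cooling_lambda = 0.4,
                  noise_sd = 0.1, euler_step = 0.1),
      low = list(mode = "low", gain_alpha = 0.278180, cooling_lambda = 0.002,
                 noise_sd = 0.05, euler_step = 0.1)
    ),
    cohort = list(
      n_participants = 7,
      variability_cv = 0.17,     # between-participant CV of work-rate scale
      day_to_day_cv = 0.088,     # within-participant day-to-day CV
      age_range = c(25, 52),
      hr_rest_mean = 65,
      hr_rest_sd = 5
    ),
    fatigue = list(
      onset_ref = 7,             # minutes to onset at the reference HR
      hr_ref = 130,              # BPM; reference (vigorous) heart rate
      slope = 0.8,               # minutes of onset gained per BPM below hr_ref
      decay_rate = 0.03,         # fraction of power lost/min at reference intensity
      decay_intensity_exp = 2,   # decay scales with (rel. power / ref power)^exp
      power_floor = 0.5,         # fraction of initial power the decay bottoms at
      evening_factor = 2.75,     # multiplies decay, divides onset after cutoff
      evening_cutoff = "17:00",
      home_effort_gain = 1.092,  # home dose-taking intensity vs calibration bout
      hr_noise_sd = 10,          # BPM; the control band around the HR target
      hr_drift_rate = 1.5        # BPM/min rise after onset when power is held
    ),
    schedule = list(
      adherence_prob = 0.6,
      p_afternoon = 0.64,
      afternoon_window = c("13:00", "16:30"),
      evening_window = c("18:00", "21:00")
    ),
    analysis = list(
      smooth_window = 3,
      slope_tol = c(high = 0.5, low = 0.05),
      hr_drift_tol = 15,
      lwo_drop_tol = 0.05,
      persistence = 3,
      tie_break = "standard_score",
      alpha = 0.05
    ),
    seeds = list(master = 20160822)
  )
}

#' Read a study configuration file
#'
#' Reads a YAML configuration and merges it over [study_defaults()]. Unknown
#' keys are rejected with a warning that lists them, so typos in a config do
#' not silently fall back to defaults.
#'
#' @param path Path to a YAML file. Keys mirror the structure of
#'   [study_defaults()], e.g. `device: low: cooling_lambda: 0.002`.
#' @return The merged configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  defaults <- study_defaults()
  merge_checked(defaults, user %||% list(), prefix = "")
}

# Recursive merge of `user` over `defaults`; warns on keys absent from defaults.
merge_checked <- function(defaults, user, prefix = "") {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    warning("unknown config keys ignored: ",
            paste0(prefix, unknown, collapse = ", "), call. = FALSE)
    user <- user[setdiff(names(user), unknown)]
  }
  for (key in names(user)) {
    defaults[[key]] <- if (is.list(defaults[[key]]) && is.list(user[[key]])) {
      merge_checked(defaults[[key]], user[[key]], prefix = paste0(prefix, key, "."))
    } else {
      user[[key]]
    }
  }
  defaults
}
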