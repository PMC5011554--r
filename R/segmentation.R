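#' Segment a bout's temperature trace into its four phases
#'
#' Decomposes a device trace into the characteristic phases of an exercise
#' bout: (1) initial rise, (2) plateau, (3) within-exercise decline, and
#' (4) post-cessation recovery. Phases are read off the smoothed slope:
#' rise while the slope exceeds `+slope_tol`, plateau while it stays within
#' `+-slope_tol`, decline while it is below `-slope_tol` during exercise.
#' The boundaries are reported at 1-minute resolution as `t1` (end of rise),
#' `t2` (end of plateau), `t3` (end of exercise) and `t4` (end of the
#' recording); the plateau may be empty (`t1 == t2`) and so may the decline
#' (`t2 == t3`), as in a fatigue-free bout. A trace with no detectable rise
#' is returned flagged `degenerate`.
#'
#' @param trace A [sensor_trace()] of at least 5 minutes.
#' @param smooth_window Slope window in minutes.
#' @param slope_tol Slope tolerance in degC/min separating "steady" from
#'   rising/falling; defaults to 0.5 (high mode) or 0.05 (low mode). The
#'   study identified phases by eye; this tolerance is the package's
#'   operationalization of that judgement.
#' @param exercise_end Minute exercise stopped, if known from bout metadata.
#'   When absent it is detected as the steepest sustained negative slope
#'   change; if none is found the trace is assumed to end with exercise.
#' @return An object of class `phase_segmentation`: boundaries `t1`-`t4`, a
#'   per-sample `phase` factor (`rise`, `plateau`, `decline`, `recovery`),
#'   `plateau_median` (degC; NA when the plateau is empty) and a
#'   `degenerate` flag.
#' @export
segment_phases <- function(trace, smooth_window = 3, slope_tol = NULL,
                           exercise_end = NULL) {
  stopifnot(inherits(trace, "sensor_trace"))
  if (nrow(trace) < 5) {
    stop("trace too short to segment (need >= 5 minutes)", call. = FALSE)
  }
  mode <- attr(trace, "mode")
  slope_tol <- slope_tol %||%
    unname(study_defaults()$analysis$slope_tol[mode])
  s <- moving_slope(trace$minute, trace$delta_t_c, smooth_window)
  n <- nrow(trace)
  t_end <- trace$minute[n]

  if (is.null(exercise_end)) {
    exercise_end <- detect_exercise_end(trace$minute, s, slope_tol)
  }
  if (exercise_end > t_end) exercise_end <- t_end

  ex <- trace$minute <= exercise_end
  degenerate <- max(trace$delta_t_c[ex]) < max(5 * stats::sd(utils::tail(trace$delta_t_c, 5)), 0.5) ||
    !any(s[ex] > slope_tol)
  if (degenerate) {
    seg <- list(t1 = 0, t2 = 0, t3 = exercise_end, t4 = t_end,
                phase = factor(rep("plateau", n),
                               levels = c("rise", "plateau", "decline", "recovery")),
                plateau_median = NA_real_, degenerate = TRUE,
                slope_tol = slope_tol)
    class(seg) <- "phase_segmentation"
    return(seg)
  }

  # end of initial rise: first minute the smoothed slope falls to <= slope_tol
  in_ex <- which(ex)
  rise_break <- which(s[in_ex] <= slope_tol & trace$minute[in_ex] > 0)[1]
  t1 <- if (is.na(rise_break)) exercise_end else trace$minute[in_ex][rise_break]

  # end of plateau: first post-rise minute with a sustained negative slope
  after <- in_ex[trace$minute[in_ex] >= t1]
  neg <- s[after] < -slope_tol
  t2 <- exercise_end
  if (length(neg) >= 2) {
    sustained <- which(neg & c(neg[-1], FALSE))[1]  # two consecutive minutes
    if (!is.na(sustained)) t2 <- trace$minute[after][sustained]
  }
  if (t2 < t1) t2 <- t1
  t3 <- exercise_end

  phase <- ifelse(trace$minute < t1, "rise",
                  ifelse(trace$minute < t2, "plateau",
                         ifelse(trace$minute <= t3, "decline", "recovery")))
  phase[trace$minute >= t1 & trace$minute < t2] <- "plateau"
  if (t2 == t3) phase[trace$minute >= t1 & trace$minute <= t3] <- "plateau"
  phase <- factor(phase, levels = c("rise", "plateau", "decline", "recovery"))

  plateau_idx <- which(trace$minute >= t1 & trace$minute <= t2)
  plateau_median <- if (t2 > t1) stats::median(trace$delta_t_c[plateau_idx]) else NA_real_

  seg <- list(t1 = t1, t2 = t2, t3 = t3, t4 = t_end, phase = phase,
              plateau_median = plateau_median, degenerate = FALSE,
              slope_tol = slope_tol)
  class(seg) <- "phase_segmentation"
  seg
}

# Exercise end = start of the steepest sustained fall, provided the fall is
# clearly steeper than anything during exercise (post-cessation cooling).
detect_exercise_end <- function(minute, slope, slope_tol) {
  n <- length(slope)
  drops <- which(slope < -3 * slope_tol)
  if (length(drops) == 0) return(minute[n])
  # require the negative slope to persist to the end of the trace
  cand <- drops[vapply(drops, function(i) all(slope[i:n] < -slope_tol), logical(1))]
  if (length(cand) == 0) return(minute[n])
  minute[cand[1]]
}

#' @export
print.phase_segmentation <- function(x, ...) {
  if (x$degenerate) {
    cat("<phase_segmentation> degenerate (no detectable rise)\n")
  } else {
    cat(sprintf("<phase_segmentation> rise 0-%g, plateau %g-%g, decline %g-%g, recovery %g-%g min (plateau median %.1f degC)\n",
                x$t1, x$t1, x$t2, x$t2, x$t3, x$t3, x$t4, x$plateau_median))
  }
  invisible(x)
}

#' Detect fatigue onset from the joint work-output/heart-rate behaviour
#'
#' A bout is fatigue-free when both the work output (LWO) and the heart rate
#' stay steady for the entire exercise duration. Fatigue manifests either as
#' a decline of the estimated work rate at steady heart rate
#' (`lwo_decline_steady_hr`) or as a heart-rate rise at steady work rate
#' (`hr_rise_steady_lwo`); the onset is the first minute either steadiness is
#' lost. Heart-rate steadiness uses a Theil-Sen median slope over the
#' exercise portion (total drift <= `hr_drift_tol`); work-rate steadiness
#' uses the deconvolved power signal from [estimate_power()], which must
#' never fall below `(1 - lwo_drop_tol)` of its steady median for
#' `persistence` consecutive minutes. Detected violations are backdated to
#' the start of the sustained deviation (heart-rate onsets via a
#' least-squares hinge fit), so the reported onset estimates when the decline
#' began rather than when it crossed the tolerance.
#'
#' @param bout A [simulate_bout()] result (or a list with `sensor`, `hr`,
#'   `duration`). A missing `hr` trace restricts detection to the work-output
#'   mechanism and flags the assessment `partial`.
#' @param device The [device_params()] the sensor trace was recorded with.
#' @param criteria List with `hr_drift_tol` (BPM over the bout),
#'   `lwo_drop_tol` (fraction), `persistence` (minutes); defaults from
#'   [study_defaults()].
#' @param smooth_window Smoothing window in minutes.
#' @param tie_break When both mechanisms fail in the same minute:
#'   `"standard_score"` attributes the bout to the signal deviating by more
#'   standard-score units.
#' @return An object of class `fatigue_assessment`: `fatigue_free`,
#'   `onset_minute` (NA when fatigue-free), `mechanism`
#'   (`lwo_decline_steady_hr`, `hr_rise_steady_lwo` or `none`), `hr_steady`,
#'   `lwo_steady`, `partial`.
#' @export
detect_fatigue <- function(bout, device,
                           criteria = study_defaults()$analysis,
                           smooth_window = 3,
                           tie_break = c("standard_score", "lwo", "hr")) {
  tie_break <- match.arg(tie_break)
  stopifnot(inherits(device, "device_params"))
  sensor <- bout$sensor
  duration <- bout$duration %||% sensor$minute[nrow(sensor)]
  if (duration < 10) stop("exercise portion must be >= 10 minutes", call. = FALSE)
  hr <- bout$hr
  partial <- is.null(hr)

  hr_drift_tol <- criteria$hr_drift_tol %||% 15
  lwo_drop_tol <- criteria$lwo_drop_tol %||% 0.05
  persistence <- criteria$persistence %||% 3

  # --- work-output steadiness on the deconvolved power signal ---
  # Low-sensitivity traces need a wide derivative window: deconvolution
  # divides by the small gain, so slope noise would otherwise swamp P-hat.
  deriv_window <- if (attr(sensor, "mode") == "low") {
    max(smooth_window, 9)
  } else {
    smooth_window
  }
  ex_sensor <- sensor[sensor$minute <= duration, , drop = FALSE]
  ex_sensor <- sensor_trace(ex_sensor$minute, ex_sensor$delta_t_c,
                            attr(sensor, "mode"))
  p_hat <- estimate_power(ex_sensor, device, deriv_window)$power
  p_sm <- moving_mean(p_hat, smooth_window)
  margin <- deriv_window %/% 2 + 1
  interior <- seq(margin + 1, length(p_sm) - margin)
  if (length(interior) < 4) stop("trace too short for fatigue assessment", call. = FALSE)
  # steady reference level: the larger of two early block medians, so a
  # decline already under way late in the baseline window cannot drag it down
  blk1 <- interior[seq_len(min(5, length(interior)))]
  blk2 <- interior[pmin(seq(6, 10), length(interior))]
  lwo_base <- max(stats::median(p_sm[blk1]), stats::median(p_sm[blk2]))
  lwo_sd <- max(stats::mad(p_sm[blk1]), 1e-6)
  # propagated sensor noise on the smoothed power estimate: the LS slope of a
  # window of white noise has sd noise_sd * sqrt(12 / (w (w^2 - 1))); a drop
  # must clear both the relative tolerance and 4x this noise scale, so weak
  # work rates are not flagged on sensor noise alone
  dw <- deriv_window
  sigma_sm <- device$noise_sd * sqrt(12 / (dw * (dw^2 - 1))) /
    device$gain_alpha / sqrt(smooth_window)
  drop_thr <- max(lwo_drop_tol * lwo_base, 4 * sigma_sm)
  below <- p_sm[interior] < lwo_base - drop_thr
  lwo_onset <- NA_real_
  run <- rle(below)
  if (any(run$values & run$lengths >= persistence)) {
    ends <- cumsum(run$lengths)
    j <- which(run$values & run$lengths >= persistence)[1]
    cross <- interior[ends[j] - run$lengths[j] + 1]
    # backdate to where the sustained deviation began (half the drop
    # threshold, so baseline noise does not drag the onset earlier)
    k <- cross
    while (k > min(interior) && p_sm[k - 1] < lwo_base - drop_thr / 2) {
      k <- k - 1
    }
    lwo_onset <- ex_sensor$minute[k]
  }
  lwo_steady <- is.na(lwo_onset)

  # --- heart-rate steadiness ---
  hr_onset <- NA_real_
  hr_steady <- TRUE
  hr_score <- 0
  if (!partial) {
    ex_hr <- hr[hr$minute <= duration, , drop = FALSE]
    b <- theil_sen_slope(ex_hr$minute, ex_hr$bpm)
    drift <- b * duration
    # a drift must both exceed the tolerance and be distinguishable from the
    # sampling jitter of the per-minute control band (a Theil-Sen slope of
    # pure SD-10 noise crosses 15 BPM in ~2% of 30-min bouts otherwise)
    sigma_hat <- max(stats::mad(diff(ex_hr$bpm)) / sqrt(2), 1e-6)
    n_hr <- nrow(ex_hr)
    slope_se <- sigma_hat * sqrt(12 / n_hr^3)
    hr_steady <- abs(drift) <= hr_drift_tol || abs(b) <= 3 * slope_se
    if (!hr_steady) {
      fit <- hinge_fit(ex_hr$minute, ex_hr$bpm)
      hr_onset <- fit$breakpoint
      hr_noise <- max(stats::mad(diff(ex_hr$bpm)) / sqrt(2), 1)
      hr_score <- abs(drift) / hr_noise
    }
  }

  lwo_score <- if (!lwo_steady) {
    (lwo_base - min(p_sm[interior])) / lwo_sd
  } else 0

  mechanism <- "none"
  onset <- NA_real_
  if (!lwo_steady && (hr_steady || partial)) {
    mechanism <- "lwo_decline_steady_hr"
    onset <- lwo_onset
  } else if (lwo_steady && !hr_steady) {
    mechanism <- "hr_rise_steady_lwo"
    onset <- hr_onset
  } else if (!lwo_steady && !hr_steady) {
    # both violated: attribute to the signal deviating by more standard-score
    # units (a marginal tolerance crossing in one signal should not outrank a
    # clear deviation in the other); tie_break can force a mechanism
    pick_lwo <- switch(tie_break,
                       standard_score = lwo_score >= hr_score,
                       lwo = TRUE, hr = FALSE)
    mechanism <- if (pick_lwo) "lwo_decline_steady_hr" else "hr_rise_steady_lwo"
    onset <- if (pick_lwo) lwo_onset else hr_onset
  }
  onset <- if (is.na(onset)) NA_real_ else min(max(onset, 0), duration)

  structure(list(
    fatigue_free = mechanism == "none",
    onset_minute = onset,
    mechanism = mechanism,
    hr_steady = hr_steady,
    lwo_steady = lwo_steady,
    partial = partial
  ), class = "fatigue_assessment")
}

#' @export
print.fatigue_assessment <- function(x, ...) {
  if (x$fatigue_free) {
    cat("<fatigue_assessment> fatigue-free (steady LWO and HR throughout)\n")
  } else {
    cat(sprintf("<fatigue_assessment> %s at minute %.1f%s\n", x$mechanism,
                x$onset_minute, if (x$partial) " [partial: no HR trace]" else ""))
  }
  invisible(x)
}
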