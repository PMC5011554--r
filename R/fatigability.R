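#' Split-half dose times of a completed dose event
#'
#' Splits a completed dose-taking into the time to reach half the dose
#' (`t_first = t_half`) and the time from half to full dose
#' (`t_second = t_full - t_half`). The identity
#' `t_first + t_second = t_full` holds exactly. Lengthening of the second
#' half relative to the first is the retrospective fatigability signal: the
#' first half-dose times of a recuperated participant are reproducible,
#' while fatigue slows the later stages of a bout.
#'
#' @param event A completed [track_dose()] `dose_event`.
#' @return Named numeric `c(t_first, t_second)` in minutes.
#' @export
#' @examples
#' split_half_times(list(completed = TRUE, t_half = 13.5, t_full = 33.8))
split_half_times <- function(event) {
  if (!isTRUE(event$completed)) {
    stop("incomplete dose event: excluded from split-half statistics",
         call. = FALSE)
  }
  c(t_first = event$t_half, t_second = event$t_full - event$t_half)
}

#' Percent by which a second mean exceeds a first
#'
#' `100 * (mean_second - mean_first) / mean_first`, the statistic used to
#' report how much longer second half-doses take than first half-doses.
#'
#' @param mean_first,mean_second Group means in any common unit;
#'   `mean_first` must be positive.
#' @return Percent difference.
#' @export
#' @examples
#' percent_longer(13.5, 20.3)  # 50.4
percent_longer <- function(mean_first, mean_second) {
  if (any(mean_first <= 0)) stop("mean_first must be > 0", call. = FALSE)
  100 * (mean_second - mean_first) / mean_first
}

#' Tabulate dose events
#'
#' @param events A list of [track_dose()] `dose_event` objects.
#' @return A data frame with one row per event.
#' @export
dose_events_table <- function(events) {
  if (inherits(events, "dose_event")) events <- list(events)
  do.call(rbind, lapply(events, function(e) {
    data.frame(participant_id = e$participant_id %||% NA_character_,
               date = as.character(e$date %||% NA),
               start_clock_time = e$start_clock_time,
               threshold_c = e$threshold_c,
               t_half = e$t_half %||% NA_real_,
               t_full = e$t_full %||% NA_real_,
               notified_at = e$notified_at %||% NA_character_,
               completed = isTRUE(e$completed),
               stringsAsFactors = FALSE)
  }))
}

# Welch comparison with a zero-variance guard; permutation alternative keeps
# the same interface. Returns list(p, flag).
compare_groups <- function(x, y, test = "welch", n_perm = 999) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    return(list(p = NA_real_, flag = "insufficient"))
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(list(p = 1, flag = "zero-variance: comparison skipped"))
  }
  if (test == "welch") {
    list(p = stats::t.test(x, y, var.equal = FALSE)$p.value, flag = NA_character_)
  } else {
    obs <- abs(mean(x) - mean(y))
    pool <- c(x, y)
    nx <- length(x)
    exceed <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pool), nx)
      abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12
    }, logical(1))
    list(p = (sum(exceed) + 1) / (n_perm + 1), flag = NA_character_)
  }
}

#' Diurnal fatigability comparison of dose events
#'
#' Groups completed dose events into afternoon (start before `cutoff`) and
#' evening sessions and computes the split-half fatigability statistics:
#' per-group means and SDs of `t_first`, `t_second` and `t_total`, the
#' percent by which mean second halves exceed mean first halves, and Welch
#' two-sample comparisons of (i) `t_second` between groups, (ii) `t_total`
#' between groups and (iii) `t_first` vs `t_second` within each group.
#' Incomplete events are excluded from the time statistics (their count is
#' reported). No multiple-comparison correction is applied; the number of
#' tests is reported alongside the p-values.
#'
#' @param events A list of [track_dose()] `dose_event` objects, or the data
#'   frame from [dose_events_table()].
#' @param cutoff Afternoon/evening boundary as `"HH:MM"`; morning sessions
#'   fold into the afternoon group.
#' @param test `"welch"` or `"permutation"`.
#' @param alpha Significance level flagged in the printout.
#' @return An object of class `fatigability_report`: a `groups` data frame
#'   (one row per group with n, means, SDs, percent_longer, within-group
#'   p-value), `between` (p-values for `t_second` and `t_total`), counts of
#'   excluded events, the test used, and significance flags at `alpha`.
#' @export
diurnal_compare <- function(events, cutoff = "17:00",
                            test = c("welch", "permutation"), alpha = 0.05) {
  test <- match.arg(test)
  tab <- if (is.data.frame(events)) events else dose_events_table(events)
  n_incomplete <- sum(!tab$completed)
  tab <- tab[tab$completed, , drop = FALSE]
  if (nrow(tab) == 0) stop("no completed dose events", call. = FALSE)
  tab$t_first <- tab$t_half
  tab$t_second <- tab$t_full - tab$t_half
  tab$t_total <- tab$t_full
  tab$group <- ifelse(clock_to_minutes(tab$start_clock_time) <
                        clock_to_minutes(cutoff), "afternoon", "evening")

  groups <- do.call(rbind, lapply(c("afternoon", "evening"), function(g) {
    d <- tab[tab$group == g, , drop = FALSE]
    if (nrow(d) < 2) {
      return(data.frame(group = g, n = nrow(d), mean_first = NA_real_,
                        sd_first = NA_real_, mean_second = NA_real_,
                        sd_second = NA_real_, mean_total = NA_real_,
                        sd_total = NA_real_, percent_longer = NA_real_,
                        p_within = NA_real_, flag = "insufficient",
                        stringsAsFactors = FALSE))
    }
    cmp <- compare_groups(d$t_first, d$t_second, test)
    data.frame(group = g, n = nrow(d),
               mean_first = mean(d$t_first), sd_first = stats::sd(d$t_first),
               mean_second = mean(d$t_second), sd_second = stats::sd(d$t_second),
               mean_total = mean(d$t_total), sd_total = stats::sd(d$t_total),
               percent_longer = percent_longer(mean(d$t_first), mean(d$t_second)),
               p_within = cmp$p, flag = cmp$flag %||% NA_character_,
               stringsAsFactors = FALSE)
  }))

  aft <- tab[tab$group == "afternoon", ]
  eve <- tab[tab$group == "evening", ]
  between <- list(
    t_second = compare_groups(aft$t_second, eve$t_second, test),
    t_total = compare_groups(aft$t_total, eve$t_total, test)
  )

  structure(list(
    groups = groups,
    between = data.frame(comparison = c("t_second", "t_total"),
                         p = c(between$t_second$p, between$t_total$p),
                         flag = c(between$t_second$flag %||% NA,
                                  between$t_total$flag %||% NA),
                         stringsAsFactors = FALSE),
    n_events = nrow(tab),
    n_incomplete = n_incomplete,
    cutoff = cutoff,
    test = test,
    alpha = alpha,
    n_tests = 4L
  ), class = "fatigability_report")
}

#' @export
print.fatigability_report <- function(x, ...) {
  cat(sprintf("Diurnal fatigability report (%s test, cutoff %s, %d completed events",
              x$test, x$cutoff, x$n_events))
  if (x$n_incomplete > 0) cat(sprintf(", %d incomplete excluded", x$n_incomplete))
  cat(")\n\n")
  g <- x$groups
  for (i in seq_len(nrow(g))) {
    if (g$n[i] < 2) {
      cat(sprintf("  %-9s insufficient events (n=%d)\n", g$group[i], g$n[i]))
      next
    }
    star <- !is.na(g$p_within[i]) && g$p_within[i] < x$alpha
    cat(sprintf("  %-9s n=%2d  first %5.1f (SD %4.1f)  second %5.1f (SD %4.1f)  total %5.1f (SD %4.1f) min\n",
                g$group[i], g$n[i], g$mean_first[i], g$sd_first[i],
                g$mean_second[i], g$sd_second[i], g$mean_total[i], g$sd_total[i]))
    cat(sprintf("            second halves %.1f%% longer; first vs second P=%.3g%s\n",
                g$percent_longer[i], g$p_within[i], if (star) " *" else ""))
  }
  cat("\n  between groups:")
  for (i in seq_len(nrow(x$between))) {
    star <- !is.na(x$between$p[i]) && x$between$p[i] < x$alpha
    cat(sprintf("  %s P=%.3g%s", x$between$comparison[i], x$between$p[i],
                if (star) " *" else ""))
  }
  cat(sprintf("\n  (%d tests, no multiplicity correction; * P<%.2f)\n",
              x$n_tests, x$alpha))
  invisible(x)
}

#' Compliance summary: notification-days per week
#'
#' Counts, per participant, the distinct calendar days with at least one
#' completed dose (a sent notification), divides by the number of weeks, and
#' aggregates across participants. Incomplete events count toward adherence
#' denominators but not toward notification days.
#'
#' @param events A list of `dose_event`s or a [dose_events_table()] frame.
#' @param weeks Program length in weeks (>= 1/7; a 15-day program is 15/7).
#' @return A list: `mean` and `sd` of notification-days/week across
#'   participants, and `per_participant` (named vector).
#' @export
compliance_summary <- function(events, weeks) {
  if (!is.numeric(weeks) || weeks <= 0) stop("weeks must be > 0", call. = FALSE)
  tab <- if (is.data.frame(events)) events else dose_events_table(events)
  if (nrow(tab) == 0 || !any(tab$completed)) {
    return(list(mean = 0, sd = NA_real_, per_participant = numeric(0)))
  }
  done <- tab[tab$completed, , drop = FALSE]
  per <- tapply(done$date, done$participant_id,
                function(d) length(unique(d))) / weeks
  per <- unlist(per)
  list(mean = mean(per), sd = stats::sd(per), per_participant = per)
}
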