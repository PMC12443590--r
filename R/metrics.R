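# Windowed blood-pressure change metrics. All windows are half-open
# [a, b) over sample timestamps, so "before the start" excludes the start
# sample itself.

window_mean <- function(series, lo, hi, what, label) {
  sel <- series$time >= lo & series$time < hi
  if (!any(sel)) {
    stop("series does not cover the ", label, " window [", lo, ", ", hi,
         ")", call. = FALSE)
  }
  vapply(what, function(ch) mean(series[[ch]][sel]), numeric(1))
}

#' Blood-pressure change over a tilt challenge
#'
#' Difference between the mean of a 60-s window before the start of the
#' tilt and the mean of a 20-s window at 3 min of the challenge (centered
#' on tilt_start + 180 s). If the tilt ended before 3 min, a 20-s window
#' before the end of the tilt is used instead.
#'
#' @param series A [bp_series()].
#' @param tilt_start,tilt_end Tilt start/end times in seconds.
#' @return A list with `sbp`, `dbp` and `hr` changes (comparison minus
#'   baseline; negative = drop).
#' @export
bp_change_tilt <- function(series, tilt_start, tilt_end) {
  stopifnot(inherits(series, "bp_series"))
  if (tilt_end <= tilt_start) stop("tilt_end must be > tilt_start",
                                   call. = FALSE)
  chans <- c("sbp", "dbp", "hr")
  base <- window_mean(series, tilt_start - 60, tilt_start, chans,
                      "pre-tilt baseline")
  cmp_win <- if (tilt_end - tilt_start >= 180) {
    c(tilt_start + 170, tilt_start + 190)
  } else {
    c(tilt_end - 20, tilt_end)
  }
  cmp <- window_mean(series, cmp_win[1], cmp_win[2], chans, "comparison")
  as.list(cmp - base)
}

#' Blood-pressure change for seated stimulation
#'
#' Mean of a 20-s window at 3 min after stimulation onset (centered on
#' stim_on + 180 s) minus the mean of a 20-s window before onset. Requires
#' the stimulation bout to last at least 3 min.
#'
#' @param series A [bp_series()].
#' @param stim_on,stim_off Stimulation start/stop times in seconds.
#' @return A list with `sbp`, `dbp` and `hr` changes.
#' @export
bp_change_seated <- function(series, stim_on, stim_off) {
  stopifnot(inherits(series, "bp_series"))
  if (stim_off - stim_on < 180) {
    stop("seated stimulation must last >= 180 s for the 3-min window",
         call. = FALSE)
  }
  chans <- c("sbp", "dbp", "hr")
  base <- window_mean(series, stim_on - 20, stim_on, chans, "pre-EES")
  cmp <- window_mean(series, stim_on + 170, stim_on + 190, chans, "3-min")
  as.list(cmp - base)
}

#' Intraoperative blood-pressure change
#'
#' Difference between the means of 30-s windows before the start of the
#' stimulation and at the end of the stimulation. If the bout is shorter
#' than 30 s the windows are computed as specified even though they
#' overlap (a warning is issued).
#'
#' @param series A [bp_series()].
#' @param stim_start,stim_end Stimulation start/end times in seconds.
#' @return A list with `sbp`, `dbp` and `hr` changes.
#' @export
bp_change_intraop <- function(series, stim_start, stim_end) {
  stopifnot(inherits(series, "bp_series"))
  if (stim_end <= stim_start) stop("stim_end must be > stim_start",
                                   call. = FALSE)
  if (stim_end - stim_start < 30) {
    warning("stimulation shorter than 30 s: windows overlap")
  }
  chans <- c("sbp", "dbp", "hr")
  base <- window_mean(series, stim_start - 30, stim_start, chans,
                      "pre-stimulation")
  cmp <- window_mean(series, stim_end - 30, stim_end, chans,
                     "end-of-stimulation")
  as.list(cmp - base)
}

#' Postprandial blood-pressure change from cuff measurements
#'
#' Mean of the cuff measures taken between 30 and 60 min after the meal
#' minus the mean of all pre-meal baseline measures.
#'
#' @param baseline_cuff Numeric vector of pre-meal cuff SBP (mm Hg).
#' @param post_time Minutes after the meal of each post measure.
#' @param post_cuff Post-meal cuff SBP values (mm Hg).
#' @return The postprandial change in mm Hg.
#' @examples
#' postprandial_delta(c(110, 112), c(35, 50, 70), c(95, 99, 130))  # -14
#' @export
postprandial_delta <- function(baseline_cuff, post_time, post_cuff) {
  if (length(baseline_cuff) < 1) stop("need >= 1 baseline measure",
                                      call. = FALSE)
  if (length(post_time) != length(post_cuff)) {
    stop("post_time and post_cuff must be equal length", call. = FALSE)
  }
  sel <- post_time >= 30 & post_time <= 60
  if (!any(sel)) {
    stop("no post-meal cuff measure within [30, 60] min", call. = FALSE)
  }
  mean(post_cuff[sel]) - mean(baseline_cuff)
}

#' Target-error metrics over a dynamic challenge
#'
#' Signed target error `e(t) = SBP(t) - target` evaluated from 1 min
#' before the challenge to 1 min after its end; reports the signed mean,
#' the mean absolute error and the error variability (sample s.d. of the
#' error).
#'
#' @param series A [bp_series()].
#' @param target SBP target in mm Hg.
#' @param challenge_start,challenge_end Challenge bounds in seconds.
#' @return An object of class `challenge_metrics` with
#'   `target_error_mean`, `target_error_mean_abs`, `error_variability`
#'   and `window`.
#' @export
challenge_errors <- function(series, target, challenge_start,
                             challenge_end) {
  stopifnot(inherits(series, "bp_series"))
  lo <- challenge_start - 60
  hi <- challenge_end + 60
  sel <- series$time >= lo & series$time < hi
  if (!any(sel) || min(series$time) > lo ||
      max(series$time) + 1 / attr(series, "fs") < hi) {
    stop("series does not cover the challenge window [", lo, ", ", hi, ")",
         call. = FALSE)
  }
  e <- series$sbp[sel] - target
  out <- list(target_error_mean = mean(e),
              target_error_mean_abs = mean(abs(e)),
              error_variability = stats::sd(e),
              window = c(start = lo, end = hi))
  class(out) <- "challenge_metrics"
  out
}

#' @export
print.challenge_metrics <- function(x, ...) {
  cat(sprintf(
    "Challenge [%g, %g) s: mean error %+.2f mm Hg (|e| %.2f), s.d. %.2f\n",
    x$window["start"], x$window["end"], x$target_error_mean,
    x$target_error_mean_abs, x$error_variability))
  invisible(x)
}

#' Centered moving-average smoothing for display
#'
#' Smooths every channel except time/angle/amplitude with a centered
#' moving average over `window` seconds; at the edges the window shrinks
#' to the available samples.
#'
#' @param series A [bp_series()].
#' @param window Window length in seconds (default 10).
#' @return A [bp_series()] with smoothed sbp/dbp/hr channels.
#' @export
smooth_display <- function(series, window = 10) {
  stopifnot(inherits(series, "bp_series"))
  fs <- attr(series, "fs")
  if (window < 1 / fs) stop("window must be >= the sample period",
                            call. = FALSE)
  half <- window / 2
  n <- nrow(series)
  sm <- function(x) {
    vapply(seq_len(n), function(i) {
      sel <- series$time >= series$time[i] - half &
        series$time < series$time[i] + half
      mean(x[sel])
    }, numeric(1))
  }
  out <- series
  out$sbp <- sm(series$sbp)
  out$dbp <- sm(series$dbp)
  out$hr <- sm(series$hr)
  out
}

#' Time from tilt onset to tilt termination
#'
#' Elapsed time from `tilt_start` to the simulator's recorded termination
#' flag or to a breach of an explicit tolerance criterion (SBP below a
#' threshold for a sustained hold), whichever applies; traces that never
#' fail are censored at the end of the record.
#'
#' @param trace A [bp_series()].
#' @param tilt_start Tilt onset in seconds.
#' @param criterion Either `NULL` (use the simulator's termination
#'   attribute, censoring if absent), or a list with `sbp` (mm Hg) and
#'   `hold` (s) to scan the trace directly. Use `criterion = list()` to
#'   disable any criterion and always censor.
#' @return A list with `time` (s from tilt_start), `event` (TRUE if the
#'   tilt was terminated, FALSE if censored).
#' @export
time_to_tilt_end <- function(trace, tilt_start, criterion = NULL) {
  stopifnot(inherits(trace, "bp_series"))
  if (tilt_start < min(trace$time) || tilt_start > max(trace$time)) {
    stop("tilt_start outside the trace", call. = FALSE)
  }
  end_time <- max(trace$time) + 1 / attr(trace, "fs")
  if (is.null(criterion)) {
    term <- attr(trace, "termination")
    if (is.finite(term) && term >= tilt_start) {
      return(list(time = term - tilt_start, event = TRUE))
    }
    return(list(time = end_time - tilt_start, event = FALSE))
  }
  if (length(criterion) == 0L) {
    return(list(time = end_time - tilt_start, event = FALSE))
  }
  dt <- 1 / attr(trace, "fs")
  sel <- trace$time >= tilt_start
  tt <- trace$time[sel]
  below <- trace$sbp[sel] < criterion$sbp & trace$angle[sel] > 0
  run_start <- NA_real_
  for (i in seq_along(tt)) {
    if (below[i]) {
      if (is.na(run_start)) run_start <- tt[i]
      if (tt[i] - run_start + dt >= criterion$hold) {
        return(list(time = tt[i] - tilt_start, event = TRUE))
      }
    } else {
      run_start <- NA_real_
    }
  }
  list(time = end_time - tilt_start, event = FALSE)
}
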