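#' Fit the amplitude-to-SBP calibration from a staircase session
#'
#' Identifies the linear operating range of EES amplitudes from a seated
#' amplitude-titration session: per-level mean SBP is computed over the
#' settled second half of each staircase level; the minimum of the range is
#' the first amplitude whose mean exceeds the 0 mA mean by at least
#' `rise_threshold`, and the maximum is the last amplitude whose mean
#' exceeds the previous level's mean by at least `rise_threshold` (the last
#' amplitude at which SBP was still increasing). An ordinary least-squares
#' regression of per-level mean SBP on amplitude over the operating range
#' yields the slope that seeds the controller.
#'
#' @param series A [bp_series()] recorded during the staircase.
#' @param schedule The [stim_schedule()] staircase that was applied.
#' @param rise_threshold Minimum mean-SBP increase counted as a response,
#'   in mm Hg (default 2, above typical 1 Hz noise).
#' @return An object of class `calibration`: `amp_min`, `amp_max`, `slope`
#'   (mm Hg/mA), `intercept`, `r_squared` and the `per_level_means` table.
#' @export
fit_calibration <- function(series, schedule, rise_threshold = 2) {
  stopifnot(inherits(series, "bp_series"), inherits(schedule, "stim_schedule"))
  n_lev <- nrow(schedule)
  if (n_lev < 3) stop("need at least 3 amplitude levels", call. = FALSE)
  ends <- c(schedule$time_s[-1], schedule$time_s[n_lev] +
              diff(utils::tail(schedule$time_s, 2)))
  if (max(series$time) + 1 / attr(series, "fs") < ends[n_lev]) {
    stop("series does not cover the staircase schedule", call. = FALSE)
  }
  means <- vapply(seq_len(n_lev), function(i) {
    lo <- (schedule$time_s[i] + ends[i]) / 2  # settled second half
    sel <- series$time >= lo & series$time < ends[i]
    if (!any(sel)) {
      stop("no samples in the settled window of level ", i, call. = FALSE)
    }
    mean(series$sbp[sel])
  }, numeric(1))
  amps <- schedule$amplitude_ma
  base <- means[1]
  rising_from_zero <- which(means - base >= rise_threshold)
  rising_from_zero <- rising_from_zero[rising_from_zero > 1]
  if (length(rising_from_zero) == 0L) {
    stop("no operating range: no level rose >= ", rise_threshold,
         " mm Hg above the 0 mA mean", call. = FALSE)
  }
  i_min <- min(rising_from_zero)
  increasing <- which(diff(means) >= rise_threshold) + 1L
  i_max <- max(increasing)
  if (i_max < i_min) i_max <- i_min
  sel <- i_min:i_max
  if (length(sel) < 2) {
    stop("fewer than 2 levels inside the operating range; cannot fit",
         call. = FALSE)
  }
  # A top level whose rise is clearly sub-linear saturated inside the
  # step; keep it as the range endpoint but drop it from the regression
  # so a partial step does not bias the slope.
  fit_sel <- sel
  if (length(sel) >= 3) {
    incs <- diff(means[sel])
    if (incs[length(incs)] < 0.9 * stats::median(incs)) {
      fit_sel <- sel[-length(sel)]
    }
  }
  fit <- stats::lm(means[fit_sel] ~ amps[fit_sel])
  sst <- sum((means[fit_sel] - mean(means[fit_sel]))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  out <- list(
    amp_min = amps[i_min], amp_max = amps[i_max],
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = min(max(r2, 0), 1),
    per_level_means = data.frame(amplitude_ma = amps, mean_sbp = means)
  )
  class(out) <- "calibration"
  out
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf(
    "Calibration: operating range [%g, %g] mA, SBP = %.2f + %.3f * amp (R2 %.3f)\n",
    x$amp_min, x$amp_max, x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' Seed controller gains from a calibration
#'
#' The proportional gain is initialized from the calibration regression.
#' The regression slope has units mm Hg per mA while the controller maps a
#' pressure error (mm Hg) to an amplitude (mA), so the slope is inverted:
#' `kp = 1 / slope` (mA per mm Hg). Integral and derivative gains follow
#' configurable Ziegler-Nichols-style ratios of kp (`ki = kp / ti`,
#' `kd = kp * td`), standing in for the manual tuning performed over a
#' single 70-degree tilt. Amplitude bounds are 0 mA to the calibrated
#' maximum.
#'
#' @param cal A `calibration` from [fit_calibration()].
#' @param target SBP target in mm Hg (plausible range 60-200).
#' @param ti Integral time in seconds (default 10, tuned over a single
#'   70-degree tilt of the default twin).
#' @param td Derivative time in seconds (default 0).
#' @param ... Further arguments passed to [controller_config()].
#' @return A [controller_config()].
#' @examples
#' \dontrun{initial_gains(cal, target = 110)}
#' @export
initial_gains <- function(cal, target, ti = 10, td = 0, ...) {
  stopifnot(inherits(cal, "calibration"))
  if (!is.finite(cal$slope) || cal$slope <= 0) {
    stop("calibration slope must be > 0 (controller polarity undefined)",
         call. = FALSE)
  }
  if (target < 60 || target > 200) {
    stop("target outside the plausible SBP range [60, 200]", call. = FALSE)
  }
  kp <- 1 / cal$slope
  controller_config(kp = kp, ki = if (ti > 0) kp / ti else 0,
                    kd = kp * td, target = target,
                    amp_min = 0, amp_max = cal$amp_max, ...)
}

#' Serialize a calibration to JSON
#'
#' @param cal A `calibration`.
#' @param path Output path.
#' @return `path`, invisibly; `read_calibration` returns the object.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "calibration"))
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$per_level_means <- as.data.frame(obj$per_level_means)
  class(obj) <- "calibration"
  obj
}
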