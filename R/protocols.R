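#' Tilt-table protocol
#'
#' A tilt protocol is an ordered sequence of table positions (angle from
#' horizontal, hold duration). The table moves between consecutive positions
#' at a finite `transition_rate`; the transition is part of the incoming
#' segment's hold time, so the implied angle trace is continuous and
#' piecewise linear.
#'
#' @param angle Numeric vector of segment angles in degrees from horizontal,
#'   each in \[0, 90\].
#' @param duration Numeric vector of segment hold durations in seconds
#'   (strictly positive), recycled against `angle`.
#' @param transition_rate Table verticalization speed in degrees per second.
#'   The default 2 deg/s reaches 70 degrees in 35 s, within the clinical
#'   bound of 45 s.
#' @return An object of class `tilt_protocol`: a data frame with columns
#'   `angle_deg` and `duration_s` plus a `transition_rate` attribute.
#' @examples
#' tilt_protocol(c(0, 70), c(300, 600))
#' @export
tilt_protocol <- function(angle, duration, transition_rate = 2) {
  angle <- as.numeric(angle)
  duration <- rep(as.numeric(duration), length.out = length(angle))
  if (length(angle) < 1L) {
    stop("a tilt protocol needs at least one segment", call. = FALSE)
  }
  if (any(!is.finite(angle)) || any(angle < 0) || any(angle > 90)) {
    stop("segment angles must be finite and within [0, 90] degrees",
         call. = FALSE)
  }
  if (any(!is.finite(duration)) || any(duration <= 0)) {
    stop("segment durations must be finite and > 0 seconds", call. = FALSE)
  }
  if (!is.finite(transition_rate) || transition_rate <= 0) {
    stop("transition_rate must be > 0 degrees per second", call. = FALSE)
  }
  out <- data.frame(angle_deg = angle, duration_s = duration)
  attr(out, "transition_rate") <- transition_rate
  class(out) <- c("tilt_protocol", "data.frame")
  out
}

#' @export
print.tilt_protocol <- function(x, ...) {
  cat("Tilt protocol:", nrow(x), "segment(s),",
      format(sum(x$duration_s)), "s total,",
      attr(x, "transition_rate"), "deg/s transitions\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Total duration of a tilt protocol in seconds
#' @param protocol A [tilt_protocol()].
#' @return Total duration in seconds.
#' @export
protocol_duration <- function(protocol) {
  stopifnot(inherits(protocol, "tilt_protocol"))
  sum(protocol$duration_s)
}

#' Formal head-up tilt challenge
#'
#' Two-segment protocol: supine baseline at 0 degrees, then a single head-up
#' tilt. Mirrors the clinical orthostatic challenge in which participants
#' are tilted up to 70 degrees, reached in under 45 s, for up to 10 min.
#'
#' @param angle Tilt angle in degrees, 0 < angle <= 90.
#' @param baseline_duration Supine baseline duration in seconds.
#' @param tilt_duration Tilt hold duration in seconds.
#' @param transition_rate Degrees per second; must reach `angle` within 45 s.
#' @return A [tilt_protocol()] with two segments.
#' @examples
#' make_formal_tilt(70, 300, 600)
#' @export
make_formal_tilt <- function(angle, baseline_duration, tilt_duration,
                             transition_rate = 2) {
  if (!is.finite(angle) || angle < 0 || angle > 90) {
    stop("angle must be within [0, 90] degrees", call. = FALSE)
  }
  if (baseline_duration <= 0 || tilt_duration <= 0) {
    stop("durations must be > 0 seconds", call. = FALSE)
  }
  if (angle > 0 && transition_rate < angle / 45) {
    stop("transition_rate too slow: must reach the tilt angle within 45 s",
         call. = FALSE)
  }
  tilt_protocol(c(0, angle), c(baseline_duration, tilt_duration),
                transition_rate = transition_rate)
}

#' Pseudo-random dynamic tilt sequence
#'
#' Seeded sequence of tilt-angle changes spanning mild to severe orthostatic
#' challenge (default eight changes between 20 and 80 degrees, each held for
#' 60-120 s). Angles are drawn uniformly on a 10-degree grid, matching
#' realistic tilt-table settings; consecutive segments are forced to differ
#' so each entry is a genuine change in angle. Hold times are uniform and
#' continuous on \[`hold_min`, `hold_max`\].
#'
#' @param seed Integer seed; identical seeds give identical protocols.
#' @param n_changes Number of tilt-angle changes (segments).
#' @param angle_min,angle_max Angle bounds in degrees.
#' @param hold_min,hold_max Hold-duration bounds in seconds.
#' @param transition_rate Degrees per second.
#' @return A [tilt_protocol()] with `n_changes` segments.
#' @examples
#' make_dynamic_tilt(seed = 1)
#' @export
make_dynamic_tilt <- function(seed, n_changes = 8, angle_min = 20,
                              angle_max = 80, hold_min = 60, hold_max = 120,
                              transition_rate = 2) {
  if (n_changes < 1) stop("n_changes must be >= 1", call. = FALSE)
  if (angle_min > angle_max) {
    stop("angle_min must be <= angle_max", call. = FALSE)
  }
  if (angle_min < 0 || angle_max > 90) {
    stop("angles must lie within [0, 90] degrees", call. = FALSE)
  }
  if (hold_min > hold_max || hold_min <= 0) {
    stop("invalid hold bounds", call. = FALSE)
  }
  grid <- seq(ceiling(angle_min / 10) * 10, angle_max, by = 10)
  grid <- grid[grid >= angle_min]
  if (length(grid) == 0L) grid <- angle_min  # degenerate narrow range
  withr::with_seed(as.integer(seed), {
    angles <- numeric(n_changes)
    angles[1] <- grid[sample.int(length(grid), 1L)]
    if (n_changes > 1) {
      for (i in 2:n_changes) {
        pool <- if (length(grid) > 1L) setdiff(grid, angles[i - 1L]) else grid
        angles[i] <- pool[sample.int(length(pool), 1L)]
      }
    }
    holds <- stats::runif(n_changes, hold_min, hold_max)
  })
  tilt_protocol(angles, holds, transition_rate = transition_rate)
}

#' Angle trace implied by a tilt protocol
#'
#' Samples the continuous table angle at arbitrary times. Within each
#' segment the table moves linearly from the previous segment's angle toward
#' the segment angle at `transition_rate`, then holds. Times beyond the
#' protocol hold the final angle; negative times hold the initial angle.
#'
#' @param protocol A [tilt_protocol()].
#' @param t Numeric vector of times in seconds (t = 0 is the protocol start).
#' @return Numeric vector of angles in degrees, same length as `t`.
#' @export
angle_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "tilt_protocol"))
  rate <- attr(protocol, "transition_rate")
  starts <- cumsum(c(0, protocol$duration_s[-nrow(protocol)]))
  ends <- cumsum(protocol$duration_s)
  ang <- protocol$angle_deg
  prev <- c(ang[1], ang[-length(ang)])  # no transition into the first segment
  vapply(t, function(ti) {
    if (ti <= 0) return(ang[1])
    i <- findInterval(ti, starts, left.open = TRUE)
    if (ti >= ends[length(ends)]) i <- length(ang)
    dt_in <- ti - starts[i]
    delta <- ang[i] - prev[i]
    if (delta == 0) return(ang[i])
    travelled <- sign(delta) * min(abs(delta), rate * dt_in)
    prev[i] + travelled
  }, numeric(1))
}

#' Stimulation schedule
#'
#' Piecewise-constant EES amplitude schedule: at each breakpoint time the
#' amplitude steps to the associated value and holds until the next
#' breakpoint. Frequency and pulse width are carried as metadata (the twin's
#' pressor model is amplitude-driven).
#'
#' @param time Numeric vector of breakpoint times in seconds, strictly
#'   increasing.
#' @param amplitude Numeric vector of amplitudes in mA, all >= 0.
#' @param frequency Stimulation frequency in Hz (default 120).
#' @param pulse_width Pulse width in microseconds (default 300).
#' @return An object of class `stim_schedule`.
#' @export
stim_schedule <- function(time, amplitude, frequency = 120,
                          pulse_width = 300) {
  time <- as.numeric(time)
  amplitude <- as.numeric(amplitude)
  if (length(time) != length(amplitude) || length(time) < 1L) {
    stop("time and amplitude must be equal-length, non-empty", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("breakpoint times must be strictly increasing", call. = FALSE)
  }
  if (any(amplitude < 0)) stop("amplitudes must be >= 0 mA", call. = FALSE)
  if (frequency <= 0 || pulse_width <= 0) {
    stop("frequency and pulse_width must be positive", call. = FALSE)
  }
  out <- data.frame(time_s = time, amplitude_ma = amplitude)
  attr(out, "frequency") <- frequency
  attr(out, "pulse_width") <- pulse_width
  class(out) <- c("stim_schedule", "data.frame")
  out
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat("Stimulation schedule:", nrow(x), "breakpoint(s),",
      attr(x, "frequency"), "Hz,", attr(x, "pulse_width"), "us\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Amplitude of a schedule at arbitrary times
#'
#' @param schedule A [stim_schedule()].
#' @param t Numeric vector of times in seconds.
#' @return Amplitudes in mA (0 before the first breakpoint; the last value
#'   holds afterwards).
#' @export
amplitude_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "stim_schedule"))
  idx <- findInterval(t, schedule$time_s)
  ifelse(idx == 0, 0, schedule$amplitude_ma[pmax(idx, 1L)])
}

#' Amplitude-titration staircase
#'
#' The calibration staircase: amplitude increases by `step` mA every
#' `interval` seconds, starting at 0 mA, up to `max_amplitude`.
#'
#' @param step Amplitude increment in mA (default 1 mA).
#' @param interval Dwell time per level in seconds (default 60 s).
#' @param max_amplitude Maximum amplitude in mA.
#' @param frequency,pulse_width Passed to [stim_schedule()].
#' @return A [stim_schedule()] with levels 0, step, 2*step, ...
#' @examples
#' make_staircase(1, 60, 3)
#' @export
make_staircase <- function(step = 1, interval = 60, max_amplitude,
                           frequency = 120, pulse_width = 300) {
  if (step <= 0 || interval <= 0) {
    stop("step and interval must be positive", call. = FALSE)
  }
  if (max_amplitude < step) {
    stop("max_amplitude must be >= step", call. = FALSE)
  }
  amps <- seq(0, max_amplitude, by = step)
  stim_schedule(time = seq_along(amps) * interval - interval,
                amplitude = amps,
                frequency = frequency, pulse_width = pulse_width)
}

#' Read or write a tilt protocol as a YAML file
#'
#' The on-disk format is a mapping with keys `transition_rate_deg_per_s`
#' and `segments`, each segment carrying `angle_deg` and `duration_s`.
#'
#' @param protocol A [tilt_protocol()].
#' @param path File path.
#' @return `read_protocol` returns a [tilt_protocol()];
#'   `write_protocol` returns `path` invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "tilt_protocol"))
  obj <- list(
    transition_rate_deg_per_s = attr(protocol, "transition_rate"),
    segments = lapply(seq_len(nrow(protocol)), function(i) {
      list(angle_deg = protocol$angle_deg[i],
           duration_s = protocol$duration_s[i])
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$segments) || length(obj$segments) == 0L) {
    stop("protocol file has no segments: ", path, call. = FALSE)
  }
  tilt_protocol(
    angle = vapply(obj$segments, function(s) as.numeric(s$angle_deg),
                   numeric(1)),
    duration = vapply(obj$segments, function(s) as.numeric(s$duration_s),
                      numeric(1)),
    transition_rate = as.numeric(obj$transition_rate_deg_per_s)
  )
}
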