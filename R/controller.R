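#' Closed-loop controller configuration
#'
#' PID controller with EWMA input smoothing, a symmetric deadband around
#' the target, an integral forgetting factor, an anti-windup penalty
#' applied while the output is pinned at an amplitude bound, and ramped
#' output changes for participant comfort.
#'
#' @param kp Proportional gain, mA per mm Hg.
#' @param ki Integral gain, mA per (mm Hg s).
#' @param kd Derivative gain, mA s per mm Hg.
#' @param target SBP target in mm Hg.
#' @param deadband Half-width of the target range in mm Hg (default 3):
#'   no actuation change while the smoothed SBP is within target +/-
#'   deadband.
#' @param integral_forget Per-step forgetting factor rho on the integral,
#'   in (0, 1]. Default 0.999 at 1 Hz control (integral half-life ~11.5
#'   min): long enough to hold a sustained orthostatic load, short enough
#'   to bound drift across a session.
#' @param windup_penalty Per-step factor gamma in (0, 1] applied to the
#'   integral when the clipped command is unchanged at a bound (1 disables
#'   the anti-windup penalty; default 0.9).
#' @param ramp_step,ramp_interval,ramp_trigger Output ramping: changes
#'   larger than `ramp_trigger` mA are applied in `ramp_step` mA increments
#'   every `ramp_interval` s (defaults 0.5 mA per 500 ms).
#' @param amp_min,amp_max Amplitude bounds in mA (default minimum 0 mA;
#'   maximum is participant dependent, typically from calibration).
#' @param ewma_window Smoothing window in seconds (default 3).
#' @param ewma_forget Smoothing forgetting factor in (0, 1) (default 0.3).
#' @param ewma_mode `"decay"` (weights (1 - forget)^lag, default) or
#'   `"update"` (forget is the recursive update weight, i.e. weights
#'   forget * (1 - forget)^lag): the two published-compatible readings of
#'   an EWMA forgetting factor. Both are window-truncated and normalized,
#'   so they coincide.
#' @param control_period Controller update period in seconds (default 1).
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(kp, ki = 0, kd = 0, target,
                              deadband = 3, integral_forget = 0.999,
                              windup_penalty = 0.9,
                              ramp_step = 0.5, ramp_interval = 0.5,
                              ramp_trigger = 0.5,
                              amp_min = 0, amp_max,
                              ewma_window = 3, ewma_forget = 0.3,
                              ewma_mode = c("decay", "update"),
                              control_period = 1) {
  ewma_mode <- match.arg(ewma_mode)
  cfg <- list(kp = kp, ki = ki, kd = kd, target = target,
              deadband = deadband, integral_forget = integral_forget,
              windup_penalty = windup_penalty, ramp_step = ramp_step,
              ramp_interval = ramp_interval, ramp_trigger = ramp_trigger,
              amp_min = amp_min, amp_max = amp_max,
              ewma_window = ewma_window, ewma_forget = ewma_forget,
              ewma_mode = ewma_mode, control_period = control_period)
  nums <- cfg[setdiff(names(cfg), "ewma_mode")]
  if (!all(vapply(nums, function(x) is.numeric(x) && length(x) == 1 &&
                    is.finite(x), logical(1)))) {
    stop("controller parameters must be finite scalars", call. = FALSE)
  }
  if (cfg$deadband < 0) stop("deadband must be >= 0", call. = FALSE)
  if (cfg$integral_forget <= 0 || cfg$integral_forget > 1) {
    stop("integral_forget must be in (0, 1]", call. = FALSE)
  }
  if (cfg$windup_penalty <= 0 || cfg$windup_penalty > 1) {
    stop("windup_penalty must be in (0, 1]", call. = FALSE)
  }
  if (cfg$amp_min >= cfg$amp_max) {
    stop("amp_min must be < amp_max", call. = FALSE)
  }
  if (cfg$ewma_forget <= 0 || cfg$ewma_forget >= 1) {
    stop("ewma_forget must be in (0, 1)", call. = FALSE)
  }
  if (cfg$control_period <= 0 || cfg$ramp_step <= 0 ||
      cfg$ramp_interval <= 0 || cfg$ramp_trigger < 0) {
    stop("periods and ramp parameters must be positive", call. = FALSE)
  }
  class(cfg) <- "controller_config"
  cfg
}

#' @export
print.controller_config <- function(x, ...) {
  cat(sprintf(
    "PID controller: kp %.4g, ki %.4g, kd %.4g -> target %g +/- %g mm Hg\n",
    x$kp, x$ki, x$kd, x$target, x$deadband))
  cat(sprintf("  amplitude [%g, %g] mA, ramp %g mA / %g s (trigger %g mA)\n",
              x$amp_min, x$amp_max, x$ramp_step, x$ramp_interval,
              x$ramp_trigger))
  cat(sprintf("  integral forget %g, windup penalty %g, EWMA %gs/%g (%s)\n",
              x$integral_forget, x$windup_penalty, x$ewma_window,
              x$ewma_forget, x$ewma_mode))
  invisible(x)
}

#' Fresh controller state
#'
#' @param config A [controller_config()].
#' @param amplitude Initial commanded amplitude in mA (clipped to bounds).
#' @return An object of class `controller_state`: integral, previous error,
#'   previous clipped command, emitted amplitude and ramp clock.
#' @export
controller_state <- function(config, amplitude = config$amp_min) {
  a <- min(max(amplitude, config$amp_min), config$amp_max)
  st <- list(integral = 0, previous_error = 0, previous_command = a,
             active = FALSE, emitted = a, ramp_target = a,
             last_ramp_time = -Inf)
  class(st) <- "controller_state"
  st
}

#' Exponentially weighted moving-average smoothing
#'
#' Smooths the most recent sample of a systolic-pressure stream with a
#' window-truncated, normalized exponential weighting: samples inside the
#' trailing `window` seconds get weight `(1 - forget)^lag` (lag 0 =
#' newest), normalized to sum to one. The output therefore always lies
#' within the range of the windowed samples.
#'
#' @param samples Numeric vector, oldest first, newest last.
#' @param window Window length in seconds (default 3).
#' @param forget Forgetting factor in (0, 1) (default 0.3).
#' @param fs Sampling rate in Hz (default 1).
#' @param mode `"decay"` or `"update"`; see [controller_config()]. The two
#'   modes differ only by a constant factor and give identical normalized
#'   output; the switch is kept to document the interpretation.
#' @return The smoothed value of the newest sample.
#' @examples
#' ewma_smooth(c(100, 110, 120))  # (120 + 0.7*110 + 0.49*100) / 2.19
#' @export
ewma_smooth <- function(samples, window = 3, forget = 0.3, fs = 1,
                        mode = c("decay", "update")) {
  mode <- match.arg(mode)
  if (length(samples) < 1L) stop("need at least one sample", call. = FALSE)
  if (forget <= 0 || forget >= 1) {
    stop("forget must be in (0, 1)", call. = FALSE)
  }
  k <- min(length(samples), max(1L, floor(window * fs)))
  x <- rev(utils::tail(samples, k))     # newest first
  w <- (1 - forget)^(seq_len(k) - 1)
  if (mode == "update") w <- forget * w  # cancels in the normalization
  sum(w * x) / sum(w)
}

#' One PID update
#'
#' Computes the error `e = target - smoothed_sbp`. While the controller is
#' idle and the error lies inside the deadband, no actuation change is
#' made: the previous clipped command is held and the integral is frozen
#' (the target range absorbs intrinsic blood-pressure variability). An
#' error beyond the deadband activates the controller, which then corrects
#' until the error has crossed zero and re-entered the band, at which
#' point it re-arms and holds again. While active, the integral is updated
#' as `integral <- rho * integral + e * dt`, the derivative is the
#' backward difference of the error, and the raw command
#' `kp*e + ki*integral + kd*derivative` is clipped to the amplitude
#' bounds. If the clipped command is unchanged from the previous step and
#' sits at a bound, the integral is multiplied by the windup penalty
#' gamma.
#'
#' @param config A [controller_config()].
#' @param state A [controller_state()].
#' @param smoothed_sbp Smoothed SBP in mm Hg.
#' @param dt Time since the previous update in seconds.
#' @return A list with `command` (clipped amplitude, mA) and the updated
#'   `state`.
#' @export
pid_step <- function(config, state, smoothed_sbp, dt) {
  if (!is.finite(smoothed_sbp) || dt <= 0) {
    stop("smoothed_sbp must be finite and dt > 0", call. = FALSE)
  }
  e <- config$target - smoothed_sbp
  hold <- function(state) {
    state$previous_error <- 0
    list(command = state$previous_command, state = state)
  }
  if (!isTRUE(state$active)) {
    if (abs(e) <= config$deadband) return(hold(state))
    state$active <- TRUE
  } else {
    crossed <- state$previous_error != 0 &&
      (e == 0 || e * state$previous_error < 0)
    if (crossed && abs(e) <= config$deadband) {
      state$active <- FALSE
      return(hold(state))
    }
  }
  state$integral <- config$integral_forget * state$integral + e * dt
  deriv <- (e - state$previous_error) / dt
  u <- config$kp * e + config$ki * state$integral + config$kd * deriv
  cmd <- min(max(u, config$amp_min), config$amp_max)
  if (cmd == state$previous_command &&
      (cmd <= config$amp_min || cmd >= config$amp_max)) {
    state$integral <- config$windup_penalty * state$integral
  }
  state$previous_error <- e
  state$previous_command <- cmd
  list(command = cmd, state = state)
}

#' Ramped output stage
#'
#' Applies commanded amplitude changes at most `ramp_trigger` mA at once;
#' larger changes are walked toward the command in `ramp_step` mA
#' increments every `ramp_interval` seconds. A new command supersedes any
#' ramp in progress.
#'
#' @param config A [controller_config()].
#' @param state A [controller_state()].
#' @param raw_amplitude Commanded amplitude in mA (within bounds).
#' @param now Current time in seconds.
#' @return A list with `amplitude` (the emitted value, mA) and the updated
#'   `state`.
#' @export
ramp_output <- function(config, state, raw_amplitude, now) {
  if (raw_amplitude < config$amp_min - 1e-12 ||
      raw_amplitude > config$amp_max + 1e-12) {
    stop("raw_amplitude outside the configured bounds", call. = FALSE)
  }
  state$ramp_target <- raw_amplitude
  gap <- state$ramp_target - state$emitted
  if (abs(gap) <= config$ramp_trigger + 1e-12) {
    state$emitted <- state$ramp_target
    state$last_ramp_time <- now
    return(list(amplitude = state$emitted, state = state))
  }
  if (!is.finite(state$last_ramp_time)) state$last_ramp_time <- now - config$ramp_interval
  n_steps <- floor((now - state$last_ramp_time) / config$ramp_interval + 1e-9)
  if (n_steps > 0) {
    move <- min(abs(gap), n_steps * config$ramp_step)
    state$emitted <- state$emitted + sign(gap) * move
    state$last_ramp_time <- state$last_ramp_time +
      n_steps * config$ramp_interval
  }
  list(amplitude = state$emitted, state = state)
}

# Closed-loop policy shared by run_closed_loop (PID) and run_imu_loop
# (position map): `command_fun(t, sbp_history)` returns the clipped target
# command at each control update; ramping is applied every simulator step.
make_ramped_policy <- function(config, dt, command_fun, state_env) {
  st <- controller_state(config)
  log_rows <- list()
  force(state_env)
  policy <- function(i, t, sbp) {
    state_env$sbp_buf <- c(state_env$sbp_buf, sbp)
    nkeep <- max(1L, ceiling(config$ewma_window / dt))
    if (length(state_env$sbp_buf) > nkeep) {
      state_env$sbp_buf <-
        utils::tail(state_env$sbp_buf, nkeep)
    }
    if (t %% config$control_period < dt - 1e-9 || i == 1L) {
      cmd <- command_fun(t, state_env$sbp_buf, st)
      st <<- cmd$state
      state_env$raw <- cmd$command
    }
    r <- ramp_output(config, st, state_env$raw, t)
    st <<- r$state
    state_env$log[[length(state_env$log) + 1L]] <-
      c(time = t, error = config$target - sbp,
        integral = st$integral, raw_command = state_env$raw,
        emitted = r$amplitude)
    r$amplitude
  }
  policy
}

run_ramped_loop <- function(params, protocol, config, duration, seed,
                            command_fun) {
  dt <- config$control_period
  env <- new.env(parent = emptyenv())
  env$sbp_buf <- numeric(0)
  env$raw <- config$amp_min
  env$log <- list()
  policy <- make_ramped_policy(config, dt, command_fun, env)
  out <- simulate_engine(params, protocol, duration, dt, seed, policy,
                         amp0 = config$amp_min)
  log <- as.data.frame(do.call(rbind, env$log))
  attr(out, "log") <- log
  out
}

#' Run the closed-loop PID controller against the synthetic patient
#'
#' Couples the twin with the EWMA -> PID -> ramp chain once per control
#' period; commands apply within one simulator step. The returned series
#' carries a per-step audit log (error, integral, raw command, emitted
#' amplitude) in attribute `"log"`.
#'
#' @param params A [patient_params()].
#' @param protocol A [tilt_protocol()].
#' @param config A [controller_config()].
#' @param duration Total simulated seconds.
#' @param seed Integer seed.
#' @return A [bp_series()] with the commanded amplitude channel.
#' @export
run_closed_loop <- function(params, protocol, config, duration, seed = 1) {
  run_ramped_loop(
    params, protocol, config, duration, seed,
    command_fun = function(t, buf, st) {
      y <- ewma_smooth(buf, config$ewma_window, config$ewma_forget,
                       fs = 1 / config$control_period,
                       mode = config$ewma_mode)
      pid_step(config, st, y, config$control_period)
    })
}

#' Continuous (constant-amplitude) stimulation comparator
#'
#' Same harness as [run_closed_loop()] but with a fixed amplitude, the
#' comparator condition for closed-loop control.
#'
#' @param params A [patient_params()].
#' @param protocol A [tilt_protocol()].
#' @param amplitude Constant amplitude in mA.
#' @param duration Total simulated seconds.
#' @param seed Integer seed.
#' @param dt Simulator step in seconds.
#' @return A [bp_series()].
#' @export
run_continuous <- function(params, protocol, amplitude, duration, seed = 1,
                           dt = 1) {
  if (amplitude < 0) stop("amplitude must be >= 0 mA", call. = FALSE)
  simulate_patient(params, protocol, amplitude, duration, dt = dt,
                   seed = seed)
}

#' Tilt angle from a 3D accelerometer sample
#'
#' Angle between the measured gravity vector and the device's supine
#' reference axis, from the arccosine of the normalized dot product.
#'
#' @param accel Length-3 acceleration vector in g units.
#' @param reference Supine reference axis (default c(0, 0, 1)).
#' @return Angle in degrees, within \[0, 180\].
#' @examples
#' angle_from_accel(c(sin(70 * pi / 180), 0, cos(70 * pi / 180)))  # 70
#' @export
angle_from_accel <- function(accel, reference = c(0, 0, 1)) {
  if (length(accel) != 3 || any(!is.finite(accel))) {
    stop("accel must be a finite 3-vector", call. = FALSE)
  }
  na <- sqrt(sum(accel^2))
  nr <- sqrt(sum(reference^2))
  if (na == 0 || nr == 0) stop("zero acceleration vector", call. = FALSE)
  cosang <- sum(accel * reference) / (na * nr)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Position-to-amplitude map for IMU-based control
#'
#' Ordered bands of tilt angle mapped to postures and EES amplitudes.
#' Bands are half-open `[low, high)` except the last, which is closed at
#' its upper edge; together they must cover \[0, 90\] degrees contiguously.
#'
#' @param angle_low,angle_high Band edges in degrees.
#' @param label Posture labels (e.g. supine/seated/standing).
#' @param amplitude Amplitude per band in mA.
#' @return An object of class `position_map`.
#' @examples
#' position_map(c(0, 20, 60), c(20, 60, 90),
#'              c("supine", "seated", "standing"), c(0, 4, 8))
#' @export
position_map <- function(angle_low, angle_high, label, amplitude) {
  n <- length(angle_low)
  if (n < 1 || length(angle_high) != n || length(label) != n ||
      length(amplitude) != n) {
    stop("band vectors must be equal length", call. = FALSE)
  }
  o <- order(angle_low)
  angle_low <- angle_low[o]; angle_high <- angle_high[o]
  label <- label[o]; amplitude <- amplitude[o]
  if (angle_low[1] != 0 || angle_high[n] != 90 ||
      (n > 1 && any(abs(angle_high[-n] - angle_low[-1]) > 1e-9))) {
    stop("bands must contiguously cover [0, 90] degrees", call. = FALSE)
  }
  if (any(amplitude < 0)) stop("amplitudes must be >= 0 mA", call. = FALSE)
  out <- data.frame(angle_low = angle_low, angle_high = angle_high,
                    label = label, amplitude = amplitude)
  class(out) <- c("position_map", "data.frame")
  out
}

#' Amplitude for an angle under a position map
#'
#' @param map A [position_map()].
#' @param angle Angle in degrees (vectorized).
#' @return Amplitudes in mA.
#' @export
map_amplitude <- function(map, angle) {
  stopifnot(inherits(map, "position_map"))
  vapply(angle, function(a) {
    if (!is.finite(a) || a < 0 || a > 90) {
      stop("angle ", a, " outside the mapped range [0, 90]", call. = FALSE)
    }
    i <- findInterval(a, map$angle_low)
    map$amplitude[max(i, 1L)]
  }, numeric(1))
}

#' IMU position-based comparator controller
#'
#' At each control period the tilt angle is estimated from a simulated
#' tilt-table accelerometer (gravity vector at the true table angle plus
#' isotropic Gaussian noise), mapped through the position bands, and the
#' banded amplitude is applied with the same output ramping as the PID
#' controller.
#'
#' @param params A [patient_params()].
#' @param protocol A [tilt_protocol()].
#' @param map A [position_map()].
#' @param duration Total simulated seconds.
#' @param seed Integer seed.
#' @param accel_noise_sd Per-axis accelerometer noise in g (default 0.02).
#' @param config Optional [controller_config()] supplying ramp parameters
#'   and bounds; by default bounds span the map amplitudes.
#' @return A [bp_series()].
#' @export
run_imu_loop <- function(params, protocol, map, duration, seed = 1,
                         accel_noise_sd = 0.02, config = NULL) {
  stopifnot(inherits(map, "position_map"))
  if (is.null(config)) {
    config <- controller_config(
      kp = 0, ki = 0, kd = 0, target = params$sbp_baseline,
      amp_min = 0, amp_max = max(max(map$amplitude), 1e-6) + 1e-9)
  }
  run_ramped_loop(
    params, protocol, config, duration, seed,
    command_fun = function(t, buf, st) {
      true_angle <- angle_at(protocol, t)
      rad <- true_angle * pi / 180
      accel <- c(sin(rad), 0, cos(rad)) +
        stats::rnorm(3, 0, accel_noise_sd)
      est <- angle_from_accel(accel)
      est <- min(max(est, 0), 90)
      cmd <- min(max(map_amplitude(map, est), config$amp_min),
                 config$amp_max)
      st$previous_command <- cmd
      list(command = cmd, state = st)
    })
}
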