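#' Synthetic-patient parameters
#'
#' Parameters of the hemodynamic digital twin: a spinal-cord-injured
#' individual with orthostatic hypotension and a saturating linear pressor
#' response to epidural electrical stimulation (EES). Defaults encode the
#' clinical phenotype of medically refractory orthostatic hypotension: an
#' average systolic drop of 50 mm Hg within 3 min of a 70-degree head-up
#' tilt, and pressor responses that scale linearly with EES amplitude
#' between a response threshold and a saturation amplitude.
#'
#' @param sbp_baseline Supine, unstimulated systolic pressure (mm Hg).
#' @param dbp_baseline Supine diastolic pressure (mm Hg); used only to set
#'   the pulse pressure, since DBP is modeled as SBP minus a fixed pulse
#'   pressure.
#' @param hr_baseline Supine heart rate (bpm).
#' @param hr_orthostatic_gain Heart-rate increase at a 70-degree tilt (bpm);
#'   scaled by sin(angle)/sin(70 deg) at other angles.
#' @param orthostatic_drop_70 Steady-state SBP drop at 70 degrees (mm Hg).
#' @param drop_time_constant First-order time constant of the orthostatic
#'   drop (s). The default 50 s realizes >= 95% of the configured drop
#'   within 180 s of tilt onset, including the ~35 s table transition.
#' @param pressor_gain Pressor slope within the operating range (mm Hg/mA).
#' @param amp_threshold Lowest amplitude producing a pressor response (mA).
#' @param amp_saturation Amplitude beyond which SBP stops increasing (mA).
#' @param response_time_constant First-order time constant of the pressor
#'   onset/offset (s). Default 2 s: the neurally mediated response is fast
#'   relative to the 1 Hz pressure stream.
#' @param noise_sd Additive Gaussian noise on SBP (mm Hg per sample).
#' @param tolerance_sbp Presyncope threshold (mm Hg): tilt is flagged as
#'   terminated when SBP stays below this while tilted.
#' @param tolerance_hold Seconds below `tolerance_sbp` before termination.
#' @return An object of class `patient_params` (a validated list).
#' @export
patient_params <- function(sbp_baseline = 110,
                           dbp_baseline = 70,
                           hr_baseline = 70,
                           hr_orthostatic_gain = 15,
                           orthostatic_drop_70 = 50,
                           drop_time_constant = 50,
                           pressor_gain = 5,
                           amp_threshold = 1,
                           amp_saturation = 12,
                           response_time_constant = 2,
                           noise_sd = 2,
                           tolerance_sbp = 80,
                           tolerance_hold = 10) {
  p <- list(sbp_baseline = sbp_baseline, dbp_baseline = dbp_baseline,
            hr_baseline = hr_baseline,
            hr_orthostatic_gain = hr_orthostatic_gain,
            orthostatic_drop_70 = orthostatic_drop_70,
            drop_time_constant = drop_time_constant,
            pressor_gain = pressor_gain, amp_threshold = amp_threshold,
            amp_saturation = amp_saturation,
            response_time_constant = response_time_constant,
            noise_sd = noise_sd, tolerance_sbp = tolerance_sbp,
            tolerance_hold = tolerance_hold)
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 &&
                  is.finite(x), logical(1))
  if (!all(num)) {
    stop("all patient parameters must be finite scalars: ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  nonneg <- c("orthostatic_drop_70", "drop_time_constant", "pressor_gain",
              "response_time_constant", "noise_sd", "amp_threshold")
  bad <- nonneg[vapply(nonneg, function(k) p[[k]] < 0, logical(1))]
  if (length(bad)) {
    stop("parameters must be >= 0: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (p$amp_threshold >= p$amp_saturation) {
    stop("amp_threshold must be < amp_saturation", call. = FALSE)
  }
  if (p$sbp_baseline <= p$dbp_baseline) {
    stop("sbp_baseline must exceed dbp_baseline", call. = FALSE)
  }
  class(p) <- "patient_params"
  p
}

#' @export
print.patient_params <- function(x, ...) {
  cat("Synthetic patient:\n")
  cat(sprintf("  supine SBP/DBP %g/%g mm Hg, HR %g bpm\n",
              x$sbp_baseline, x$dbp_baseline, x$hr_baseline))
  cat(sprintf("  orthostatic drop at 70 deg: %g mm Hg (tau %g s)\n",
              x$orthostatic_drop_70, x$drop_time_constant))
  cat(sprintf(
    "  pressor: %g mm Hg/mA on (%g, %g] mA (tau %g s), noise sd %g\n",
    x$pressor_gain, x$amp_threshold, x$amp_saturation,
    x$response_time_constant, x$noise_sd))
  invisible(x)
}

#' Steady-state pressor response to EES amplitude
#'
#' Piecewise-linear, continuous, non-decreasing: zero at or below the
#' response threshold, slope `pressor_gain` up to the saturation amplitude,
#' constant plateau beyond.
#'
#' @param params A [patient_params()].
#' @param amplitude EES amplitude in mA (vectorized, all >= 0).
#' @return SBP increase in mm Hg.
#' @examples
#' p <- patient_params(pressor_gain = 3, amp_threshold = 2,
#'                     amp_saturation = 10)
#' pressor_steady_state(p, 6)  # 12 mm Hg
#' @export
pressor_steady_state <- function(params, amplitude) {
  stopifnot(inherits(params, "patient_params"))
  if (any(!is.finite(amplitude)) || any(amplitude < 0)) {
    stop("amplitude must be finite and >= 0 mA", call. = FALSE)
  }
  params$pressor_gain *
    pmax(0, pmin(amplitude, params$amp_saturation) - params$amp_threshold)
}

#' Steady-state orthostatic SBP drop at a tilt angle
#'
#' Scales the configured 70-degree drop by sin(angle)/sin(70 deg), the
#' gravitational component of the hydrostatic stress.
#'
#' @param params A [patient_params()].
#' @param angle Tilt angle in degrees, within \[0, 90\] (vectorized).
#' @return SBP drop in mm Hg (positive = pressure falls).
#' @export
orthostatic_setpoint <- function(params, angle) {
  stopifnot(inherits(params, "patient_params"))
  if (any(!is.finite(angle)) || any(angle < 0) || any(angle > 90)) {
    stop("angle must be within [0, 90] degrees", call. = FALSE)
  }
  params$orthostatic_drop_70 * sin(angle * pi / 180) / sin(70 * pi / 180)
}

#' Hemodynamic time series container
#'
#' Uniformly sampled stream of systolic/diastolic pressure, heart rate,
#' table angle and stimulation amplitude, the desk-scale analogue of a
#' 1 Hz Finometer-derived record.
#'
#' @param time,sbp,dbp,hr,angle,amplitude Equal-length numeric channels.
#' @param fs Sampling rate in Hz (time must advance by 1/fs).
#' @param termination Optional tilt-termination time in seconds (NA if the
#'   tolerance criterion was never met).
#' @return A data frame of class `bp_series` with attributes `fs` and
#'   `termination`.
#' @export
bp_series <- function(time, sbp, dbp, hr, angle, amplitude, fs = 1,
                      termination = NA_real_) {
  n <- length(time)
  chans <- list(time = time, sbp = sbp, dbp = dbp, hr = hr, angle = angle,
                amplitude = amplitude)
  if (any(vapply(chans, length, integer(1)) != n) || n < 1L) {
    stop("all channels must be non-empty and equal length", call. = FALSE)
  }
  if (any(!vapply(chans, function(x) all(is.finite(x)), logical(1)))) {
    stop("bp_series channels must be finite (no missing values)",
         call. = FALSE)
  }
  if (n > 1 && any(abs(diff(time) - 1 / fs) > 1e-8)) {
    stop("time must advance uniformly at 1/fs", call. = FALSE)
  }
  if (any(sbp < dbp)) {
    stop("sbp must be >= dbp at every sample", call. = FALSE)
  }
  out <- data.frame(time = time, sbp = sbp, dbp = dbp, hr = hr,
                    angle = angle, amplitude = amplitude)
  attr(out, "fs") <- fs
  attr(out, "termination") <- termination
  class(out) <- c("bp_series", "data.frame")
  out
}

#' @export
print.bp_series <- function(x, ...) {
  cat(sprintf(
    "bp_series: %d samples at %g Hz (%g s), SBP %.1f-%.1f mm Hg\n",
    nrow(x), attr(x, "fs"), nrow(x) / attr(x, "fs"),
    min(x$sbp), max(x$sbp)))
  if (is.finite(attr(x, "termination"))) {
    cat(sprintf("  tilt terminated at t = %g s\n", attr(x, "termination")))
  }
  utils::str(utils::head(as.data.frame(x), 3))
  invisible(x)
}

# Shared discrete-time engine. `policy` is a function(i, t, sbp) returning
# the amplitude to apply from the NEXT sample on (command latency of one
# simulator step); it may keep state in its enclosing environment. The
# first-order states use the exact exponential update so that noiseless
# traces match the closed-form step response.
simulate_engine <- function(params, protocol, duration, dt, seed, policy,
                            amp0 = 0) {
  stopifnot(inherits(params, "patient_params"),
            inherits(protocol, "tilt_protocol"))
  if (dt <= 0 || duration < dt) {
    stop("need dt > 0 and duration >= dt", call. = FALSE)
  }
  n <- floor(duration / dt)
  times <- (seq_len(n) - 1) * dt
  angles <- angle_at(protocol, times)
  a_drop <- 1 - exp(-dt / max(params$drop_time_constant, 1e-9))
  a_resp <- 1 - exp(-dt / max(params$response_time_constant, 1e-9))
  sin70 <- sin(70 * pi / 180)
  kdrop <- params$orthostatic_drop_70 / sin70

  sbp <- dbp <- hr <- amp <- numeric(n)
  pulse <- params$sbp_baseline - params$dbp_baseline
  withr::with_seed(as.integer(seed), {
    noise <- stats::rnorm(n, 0, params$noise_sd)
    drop_state <- kdrop * sin(angles[1] * pi / 180)
    pressor_state <- pressor_steady_state(params, amp0)
    a <- amp0
    below_since <- NA_real_
    termination <- NA_real_
    for (i in seq_len(n)) {
      t <- times[i]
      drop_target <- kdrop * sin(angles[i] * pi / 180)
      drop_state <- drop_state + (drop_target - drop_state) * a_drop
      ptarget <- pressor_steady_state(params, a)
      pressor_state <- pressor_state + (ptarget - pressor_state) * a_resp
      s <- params$sbp_baseline - drop_state + pressor_state + noise[i]
      if (!is.finite(s)) {
        stop("simulation produced a non-finite state at t = ", t,
             call. = FALSE)
      }
      sbp[i] <- s
      dbp[i] <- s - pulse
      hr[i] <- params$hr_baseline +
        params$hr_orthostatic_gain * sin(angles[i] * pi / 180) / sin70
      amp[i] <- a
      if (is.na(termination) && angles[i] > 0 && s < params$tolerance_sbp) {
        if (is.na(below_since)) below_since <- t
        if (t - below_since + dt >= params$tolerance_hold) termination <- t
      } else if (angles[i] <= 0 || s >= params$tolerance_sbp) {
        below_since <- NA_real_
      }
      a <- policy(i, t, s)
      if (!is.finite(a) || a < 0) {
        stop("stimulation policy returned an invalid amplitude at t = ", t,
             call. = FALSE)
      }
    }
  })
  bp_series(times, sbp, dbp, hr, angles, amp, fs = 1 / dt,
            termination = termination)
}

#' Simulate the synthetic patient
#'
#' Integrates the twin at step `dt`: SBP follows first-order dynamics
#' toward `sbp_baseline - orthostatic drop(angle) + pressor(amplitude)`,
#' with additive Gaussian noise per sample. DBP is SBP minus the supine
#' pulse pressure; HR rises with sin(angle). A tilt-termination time is
#' recorded (attribute `termination`) when SBP stays below the tolerance
#' threshold for the tolerance hold while the table is tilted.
#'
#' @param params A [patient_params()].
#' @param protocol A [tilt_protocol()].
#' @param stim A [stim_schedule()], a single constant amplitude (mA), or a
#'   function `f(t, sbp)` returning the amplitude to apply from the next
#'   sample on.
#' @param duration Total simulated time in seconds.
#' @param dt Simulator step in seconds (default 1 s, the Finometer-derived
#'   SBP rate).
#' @param seed Integer seed; identical seeds give identical traces.
#' @return A [bp_series()].
#' @examples
#' p <- patient_params(noise_sd = 0)
#' sim <- simulate_patient(p, make_formal_tilt(70, 60, 240), 0, 300, seed = 1)
#' @export
simulate_patient <- function(params, protocol, stim, duration, dt = 1,
                             seed = 1) {
  policy <-
    if (inherits(stim, "stim_schedule")) {
      function(i, t, sbp) amplitude_at(stim, t + dt)
    } else if (is.function(stim)) {
      function(i, t, sbp) stim(t, sbp)
    } else if (is.numeric(stim) && length(stim) == 1) {
      function(i, t, sbp) stim
    } else {
      stop("stim must be a stim_schedule, a constant, or a function",
           call. = FALSE)
    }
  amp0 <- if (inherits(stim, "stim_schedule")) {
    amplitude_at(stim, 0)
  } else if (is.numeric(stim)) stim else 0
  simulate_engine(params, protocol, duration, dt, seed, policy, amp0 = amp0)
}
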