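# Independent brute-force oracles, deliberately written as plain scalar
# re-implementations so they share no code with the package internals.

# EWMA: explicit weighted sum over the trailing window.
oracle_ewma <- function(samples, window = 3, forget = 0.3, fs = 1) {
  k <- min(length(samples), max(1, floor(window * fs)))
  x <- samples[seq(length(samples), length(samples) - k + 1)]
  num <- 0
  den <- 0
  for (lag in 0:(k - 1)) {
    wgt <- (1 - forget)^lag
    num <- num + wgt * x[lag + 1]
    den <- den + wgt
  }
  num / den
}

# PID recurrence: step-by-step scalar evolution with hold/re-arm deadband,
# forgetting, clipping and windup penalty in the documented order.
oracle_pid_run <- function(cfg, errors, dt = 1) {
  integral <- 0
  prev_e <- 0
  prev_cmd <- cfg$amp_min
  active <- FALSE
  cmds <- numeric(length(errors))
  for (i in seq_along(errors)) {
    e <- errors[i]
    held <- FALSE
    if (!active) {
      if (abs(e) <= cfg$deadband) held <- TRUE else active <- TRUE
    } else if (prev_e != 0 && (e == 0 || e * prev_e < 0) &&
               abs(e) <= cfg$deadband) {
      active <- FALSE
      held <- TRUE
    }
    if (held) {
      prev_e <- 0
      cmds[i] <- prev_cmd
      next
    }
    integral <- cfg$integral_forget * integral + e * dt
    deriv <- (e - prev_e) / dt
    u <- cfg$kp * e + cfg$ki * integral + cfg$kd * deriv
    cmd <- min(max(u, cfg$amp_min), cfg$amp_max)
    if (cmd == prev_cmd && (cmd <= cfg$amp_min || cmd >= cfg$amp_max)) {
      integral <- cfg$windup_penalty * integral
    }
    prev_e <- e
    prev_cmd <- cmd
    cmds[i] <- cmd
  }
  list(commands = cmds, integral = integral)
}

# Windowed mean over explicitly enumerated sample indices, half-open.
oracle_window_mean <- function(time, x, lo, hi) {
  tot <- 0
  cnt <- 0
  for (i in seq_along(time)) {
    if (time[i] >= lo && time[i] < hi) {
      tot <- tot + x[i]
      cnt <- cnt + 1
    }
  }
  tot / cnt
}

# One-line arithmetic oracles.
oracle_flow <- function(v, d) (v / 2) * (pi * d^2 / 4) * 6e7
oracle_volume <- function(L, R, r_eff = 1) (L^2 * r_eff / R) * 1e6
oracle_coverage <- function(mu, sd, p = 0.95) {
  sum(mu) + qnorm(p) * sqrt(sum(sd^2))
}

# Closed-form first-order step response.
oracle_first_order <- function(x0, xinf, tau, t) {
  xinf + (x0 - xinf) * exp(-t / tau)
}

# Default dynamic-challenge protocol used in comparator studies: 1 min
# supine, the eight-change sequence, 1 min supine.
challenge_protocol <- function(seed) {
  dyn <- make_dynamic_tilt(seed = seed)
  tilt_protocol(c(0, dyn$angle_deg, 0), c(120, dyn$duration_s, 120),
                transition_rate = attr(dyn, "transition_rate"))
}

default_calibrated_config <- function(target = 110) {
  cal <- calibrate_twin(patient_params(noise_sd = 0), seed = 99)
  initial_gains(cal, target = target)
}
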