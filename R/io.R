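# Trace serialization, fixture generation and the experiment runner.

trace_header <- c("time_s", "sbp_mmhg", "dbp_mmhg", "hr_bpm", "angle_deg",
                  "amplitude_ma")

#' Write or read a hemodynamic trace as CSV
#'
#' The on-disk format has the header
#' `time_s,sbp_mmhg,dbp_mmhg,hr_bpm,angle_deg,amplitude_ma`; missing
#' values are forbidden and time must advance uniformly.
#'
#' @param series A [bp_series()].
#' @param path File path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   [bp_series()].
#' @export
write_trace <- function(series, path) {
  stopifnot(inherits(series, "bp_series"))
  df <- data.frame(series$time, series$sbp, series$dbp, series$hr,
                   series$angle, series$amplitude)
  names(df) <- trace_header
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trace_header, names(df))
  if (length(missing_cols)) {
    stop("trace ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("trace ", path, " has no samples", call. = FALSE)
  for (cn in trace_header) {
    bad <- which(!is.finite(df[[cn]]))
    if (length(bad)) {
      stop("trace ", path, ": non-finite ", cn, " at line ", bad[1] + 1,
           call. = FALSE)
    }
  }
  dt <- diff(df$time_s)
  if (nrow(df) > 1 && (any(dt <= 0) || any(abs(dt - dt[1]) > 1e-6))) {
    stop("trace ", path, ": time must be strictly increasing and uniform",
         call. = FALSE)
  }
  fs <- if (nrow(df) > 1) 1 / dt[1] else 1
  bp_series(df$time_s, df$sbp_mmhg, df$dbp_mmhg, df$hr_bpm, df$angle_deg,
            df$amplitude_ma, fs = fs)
}

#' Generate a deterministic fixture bundle
#'
#' Writes, under `dir`, a protocol YAML, a simulated trace CSV and a JSON
#' file of metrics computed on that trace, for one of the standard study
#' conditions. Identical seeds produce byte-identical files.
#'
#' @param kind One of `"formal_tilt"` (untreated 70-degree, 10-min tilt),
#'   `"dynamic_tilt"` (eight-change 20-80 degree sequence under closed-loop
#'   control), `"staircase"` (seated 1 mA/min titration) or `"neurogram"`
#'   (synthetic microneurography record as CSV).
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param params A [patient_params()] (default twin by default).
#' @return Invisibly, a named character vector of the files written.
#' @export
make_fixture <- function(kind = c("formal_tilt", "dynamic_tilt",
                                  "staircase", "neurogram"),
                         seed, dir, params = patient_params()) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  jwrite <- function(x, f) {
    jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
    f
  }
  if (kind == "formal_tilt") {
    prot <- make_formal_tilt(70, 300, 600)
    files["protocol"] <- file.path(dir, "protocol.yaml")
    write_protocol(prot, files["protocol"])
    trace <- simulate_patient(params, prot, 0, 900, seed = seed)
    files["trace"] <- file.path(dir, "trace.csv")
    write_trace(trace, files["trace"])
    delta <- bp_change_tilt(trace, 300, 900)
    tte <- time_to_tilt_end(trace, 300)
    files["metrics"] <- jwrite(
      list(kind = kind, seed = seed, bp_change = delta,
           time_to_tilt_end = tte),
      file.path(dir, "metrics.json"))
  } else if (kind == "dynamic_tilt") {
    dyn <- make_dynamic_tilt(seed = seed)
    prot <- tilt_protocol(c(0, dyn$angle_deg, 0),
                          c(120, dyn$duration_s, 120),
                          transition_rate = attr(dyn, "transition_rate"))
    files["protocol"] <- file.path(dir, "protocol.yaml")
    write_protocol(prot, files["protocol"])
    dur <- ceiling(protocol_duration(prot))
    cal <- calibrate_twin(params, seed = seed)
    cfg <- initial_gains(cal, target = params$sbp_baseline)
    trace <- run_closed_loop(params, prot, cfg, dur, seed = seed)
    files["trace"] <- file.path(dir, "trace.csv")
    write_trace(trace, files["trace"])
    ce <- challenge_errors(trace, cfg$target, 120, dur - 120)
    files["metrics"] <- jwrite(
      list(kind = kind, seed = seed, target = cfg$target,
           target_error_mean = ce$target_error_mean,
           target_error_mean_abs = ce$target_error_mean_abs,
           error_variability = ce$error_variability),
      file.path(dir, "metrics.json"))
  } else if (kind == "staircase") {
    sched <- make_staircase(1, 60, ceiling(params$amp_saturation) + 2)
    prot <- tilt_protocol(0, (nrow(sched) + 1) * 60)
    trace <- simulate_patient(params, prot, sched,
                              (nrow(sched) + 1) * 60, seed = seed)
    files["trace"] <- file.path(dir, "trace.csv")
    write_trace(trace, files["trace"])
    cal <- fit_calibration(trace, sched)
    files["calibration"] <- file.path(dir, "calibration.json")
    write_calibration(cal, files["calibration"])
  } else {
    ng <- synth_neurogram(seed = seed, duration = 8, baseline = 3,
                          n_spikes = 6)
    files["neurogram"] <- file.path(dir, "neurogram.csv")
    utils::write.csv(
      data.frame(sample = seq_along(ng$samples), volts = ng$samples),
      files["neurogram"], row.names = FALSE, quote = FALSE)
    det <- detect_spikes(ng)
    files["metrics"] <- jwrite(
      list(kind = kind, seed = seed, fs = ng$fs,
           injected_times = attr(ng, "spike_times"),
           detected_times = det$times),
      file.path(dir, "metrics.json"))
  }
  invisible(files)
}

#' Calibrate the controller against a synthetic twin
#'
#' Convenience wrapper: runs the seated 1 mA/min staircase on the twin
#' (noise as configured) and fits the calibration.
#'
#' @param params A [patient_params()].
#' @param seed Integer seed.
#' @param step,interval Staircase parameters (default 1 mA / 60 s).
#' @param max_amplitude Top staircase level; defaults to two steps above
#'   the twin's saturation so the plateau is visible.
#' @return A `calibration`.
#' @export
calibrate_twin <- function(params, seed = 1, step = 1, interval = 60,
                           max_amplitude = NULL) {
  if (is.null(max_amplitude)) {
    max_amplitude <- ceiling(params$amp_saturation) + 2 * step
  }
  sched <- make_staircase(step, interval, max_amplitude)
  dur <- (nrow(sched)) * interval
  prot <- tilt_protocol(0, dur + interval)
  trace <- simulate_patient(params, prot, sched, dur, seed = seed)
  fit_calibration(trace, sched)
}

#' Run a full simulate-control-measure experiment
#'
#' Executes one study condition end to end and writes a JSON report of
#' the resolved configuration, seed and computed metrics, plus the trace
#' CSV. Re-running with identical configuration and seed produces
#' byte-identical outputs.
#'
#' @param params A [patient_params()].
#' @param protocol A [tilt_protocol()].
#' @param mode `"closed-loop"`, `"continuous"` or `"imu"`.
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param config A [controller_config()] (closed-loop; defaults to gains
#'   calibrated on the twin with target at the supine baseline).
#' @param amplitude Continuous-mode amplitude (defaults to the calibrated
#'   operating-range maximum).
#' @param map A [position_map()] for IMU mode (a default three-band
#'   supine/seated/standing map is built from the calibration).
#' @param duration Simulated seconds (default: the protocol duration).
#' @return Invisibly, a list with `trace`, `report` and the file paths.
#' @export
run_experiment <- function(params, protocol,
                           mode = c("closed-loop", "continuous", "imu"),
                           seed, out_dir, config = NULL, amplitude = NULL,
                           map = NULL, duration = NULL) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(duration)) duration <- ceiling(protocol_duration(protocol))
  needs_cal <- (mode == "closed-loop" && is.null(config)) ||
    (mode == "continuous" && is.null(amplitude)) ||
    (mode == "imu" && is.null(map))
  cal <- if (needs_cal) calibrate_twin(params, seed = seed) else NULL
  if (mode == "closed-loop") {
    if (is.null(config)) {
      config <- initial_gains(cal, target = params$sbp_baseline)
    }
    trace <- run_closed_loop(params, protocol, config, duration, seed)
  } else if (mode == "continuous") {
    if (is.null(amplitude)) amplitude <- cal$amp_max
    trace <- run_continuous(params, protocol, amplitude, duration, seed)
  } else {
    if (is.null(map)) {
      map <- position_map(c(0, 20, 60), c(20, 60, 90),
                          c("supine", "seated", "standing"),
                          c(0, cal$amp_max / 2, cal$amp_max))
    }
    trace <- run_imu_loop(params, protocol, map, duration, seed)
  }
  trace_path <- file.path(out_dir, "trace.csv")
  write_trace(trace, trace_path)
  target <- if (!is.null(config)) config$target else params$sbp_baseline
  ce <- challenge_errors(trace, target,
                         challenge_start = min(60, duration / 4),
                         challenge_end = duration - min(60, duration / 4))
  report <- list(
    version = as.character(utils::packageVersion("hemoloop")),
    mode = mode, seed = seed, duration_s = duration,
    target_mmhg = target,
    patient = unclass(params),
    protocol = list(angle_deg = protocol$angle_deg,
                    duration_s = protocol$duration_s,
                    transition_rate = attr(protocol, "transition_rate")),
    controller = if (!is.null(config)) unclass(config) else NULL,
    amplitude_ma = amplitude,
    metrics = list(target_error_mean = ce$target_error_mean,
                   target_error_mean_abs = ce$target_error_mean_abs,
                   error_variability = ce$error_variability,
                   termination_s = attr(trace, "termination"))
  )
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(trace = trace, report = report,
                 files = c(trace = trace_path, report = report_path)))
}
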