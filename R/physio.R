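# Auxiliary physiological computations: Doppler vessel flow, impedance
# segment volume, sympathetic neurogram processing and spike detection,
# and autonomic-dysfunction symptom scoring.

#' Volumetric flow in a vessel from Doppler velocity and diameter
#'
#' Assuming a parabolic velocity profile, the flow is
#' `Q = (FV / 2) * (pi * D^2 / 4)` with FV the Doppler velocity (m/s) and
#' D the mean B-mode diameter (m); the result is converted from m^3/s to
#' mL/min. Pass the peak (envelope) velocity for the parabolic /2
#' correction to apply, or the already-averaged mean velocity with
#' `velocity_is_mean = TRUE`, in which case no halving is performed.
#'
#' @param velocity Doppler velocity in m/s (vectorized).
#' @param diameter Mean vessel diameter in m (vectorized).
#' @param velocity_is_mean Set TRUE if `velocity` is already the
#'   cross-sectional mean (integrated Doppler curve).
#' @return Flow in mL/min.
#' @examples
#' vessel_flow(0.5, 0.005)  # 294.52 mL/min
#' @export
vessel_flow <- function(velocity, diameter, velocity_is_mean = FALSE) {
  if (any(!is.finite(velocity)) || any(velocity < 0) ||
      any(!is.finite(diameter)) || any(diameter < 0)) {
    stop("velocity and diameter must be finite and >= 0", call. = FALSE)
  }
  vbar <- if (velocity_is_mean) velocity else velocity / 2
  q_m3s <- vbar * pi * diameter^2 / 4
  q_m3s * 6e7
}

#' Total cerebral blood flow
#'
#' Sum of the flows of the left and right internal carotid and vertebral
#' arteries. Middle cerebral artery entries, if present, are ignored.
#'
#' @param measures A data frame with columns `vessel` (labels among
#'   ICA_L, ICA_R, VA_L, VA_R, MCA_L, MCA_R), `velocity` (m/s) and
#'   `diameter` (m).
#' @param velocity_is_mean Passed to [vessel_flow()].
#' @return Total CBF in mL/min.
#' @export
total_cbf <- function(measures, velocity_is_mean = FALSE) {
  required <- c("ICA_L", "ICA_R", "VA_L", "VA_R")
  if (!all(c("vessel", "velocity", "diameter") %in% names(measures))) {
    stop("measures needs columns vessel, velocity, diameter", call. = FALSE)
  }
  missing <- setdiff(required, measures$vessel)
  if (length(missing)) {
    stop("missing vessel measure(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sel <- measures[match(required, measures$vessel), ]
  sum(vessel_flow(sel$velocity, sel$diameter,
                  velocity_is_mean = velocity_is_mean))
}

#' Body-segment volume from bioelectrical impedance
#'
#' `V_geom = (L^2 * r_eff / R) * 1,000,000`, with L the segment length in
#' meters, r_eff the effective resistivity (default 1.0 ohm m) and R the
#' measured segment resistance in ohms. Volume is inversely proportional
#' to resistance, so a resistance rise reflects fluid loss.
#'
#' @param length Segment length in m (> 0).
#' @param resistance Segment resistance in ohm (> 0), vectorized.
#' @param r_eff Effective resistivity in ohm m (default 1.0).
#' @return Segment volume in the formula's units (mL for SI inputs).
#' @examples
#' segment_volume(0.3, 30)  # 3000
#' @export
segment_volume <- function(length, resistance, r_eff = 1.0) {
  if (!is.finite(length) || length <= 0) {
    stop("length must be > 0 m", call. = FALSE)
  }
  if (any(!is.finite(resistance)) || any(resistance <= 0)) {
    stop("resistance must be > 0 ohm", call. = FALSE)
  }
  (length^2 * r_eff / resistance) * 1e6
}

#' Raw microneurography record
#'
#' @param samples Numeric vector of neurogram samples (volts).
#' @param fs Sampling rate in Hz (default 20000); must exceed twice the
#'   2 kHz upper band edge.
#' @param baseline_window Two-element vector (start, end) in seconds of a
#'   stimulator-off, spike-free baseline used to scale the detection
#'   threshold.
#' @return An object of class `neurogram`.
#' @export
neurogram <- function(samples, fs = 20000, baseline_window = NULL) {
  if (fs <= 2 * 2000) {
    stop("fs must exceed twice the 2 kHz upper band edge", call. = FALSE)
  }
  if (length(samples) < fs) stop("record must be >= 1 s", call. = FALSE)
  dur <- length(samples) / fs
  if (is.null(baseline_window)) baseline_window <- c(0, min(1, dur))
  if (baseline_window[1] < 0 || baseline_window[2] > dur ||
      baseline_window[1] >= baseline_window[2]) {
    stop("baseline window must lie within the record", call. = FALSE)
  }
  out <- list(samples = as.numeric(samples), fs = fs,
              baseline_window = baseline_window)
  class(out) <- "neurogram"
  out
}

band_pass <- function(x, fs, lo = 300, hi = 2000) {
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Multiunit (mean-voltage) neurogram
#'
#' Band-pass filters the raw record at 0.3-2.0 kHz (second-order
#' Butterworth, applied forward and backward for zero phase), full-wave
#' rectifies, and leaky-integrates with a 0.1-s time constant.
#'
#' @param n A [neurogram()].
#' @param tau Integration time constant in seconds (default 0.1).
#' @return Numeric vector: the integrated (mean-voltage) neurogram,
#'   non-negative everywhere.
#' @export
process_neurogram <- function(n, tau = 0.1) {
  stopifnot(inherits(n, "neurogram"))
  rect <- abs(band_pass(n$samples, n$fs))
  alpha <- exp(-1 / (n$fs * tau))
  # single-pole leaky integrator y[k] = a y[k-1] + (1 - a) x[k]
  as.numeric(signal::filter(c(1 - alpha), c(1, -alpha), rect))
}

#' Canonical triphasic spike template
#'
#' Tri-lobed (positive-negative-positive) waveform with a dominant
#' negative main phase, built from half-sine lobes with amplitude ratio
#' 0.5 : -1 : 0.5 and duration split 25/50/25 of the total.
#'
#' @param fs Sampling rate in Hz.
#' @param duration_ms Total template duration in ms (default 15).
#' @param lobe_ratio Amplitudes of the three lobes (default
#'   c(0.5, -1, 0.5)).
#' @return Numeric vector, normalized so the trough is -1.
#' @export
triphasic_template <- function(fs, duration_ms = 15,
                               lobe_ratio = c(0.5, -1, 0.5)) {
  n <- max(12L, round(fs * duration_ms / 1000))
  n1 <- round(n / 4); n3 <- round(n / 4); n2 <- n - n1 - n3
  lobe <- function(len, a) a * sin(pi * seq_len(len) / (len + 1))
  w <- c(lobe(n1, lobe_ratio[1]), lobe(n2, lobe_ratio[2]),
         lobe(n3, lobe_ratio[3]))
  w / abs(min(w))
}

#' Detect sympathetic action-potential spikes
#'
#' Candidate events are peaks of the matched-filter response of the
#' band-passed neurogram to a triphasic template (main phase negative).
#' The deflection amplitude of each candidate is the least-squares
#' template-fit depth (projection of the signal onto the unit-trough
#' template), and events are retained when that deflection exceeds
#' `threshold_sd` times the s.d. of the band-passed neurogram over the
#' stimulator-off baseline, and the normalized cross-correlation with the
#' template exceeds `ncc_threshold`. A refractory period suppresses
#' secondary detections.
#'
#' @param n A [neurogram()] whose baseline window is spike-free.
#' @param threshold_sd Amplitude criterion in baseline s.d. units
#'   (default 4.5).
#' @param ncc_threshold Template-correlation gate (default 0.7, set so
#'   that genuine triphasic events near the amplitude floor are retained
#'   under band-limited noise while wrong-polarity or wrong-shape
#'   deflections are rejected).
#' @param template_duration_ms Template length in ms (default 15).
#' @param refractory_ms Refractory period in ms (default 20).
#' @return A list with `times` (spike centers, s), `amplitudes`
#'   (fitted deflection in baseline-s.d. units) and `baseline_sd`.
#' @export
detect_spikes <- function(n, threshold_sd = 4.5, ncc_threshold = 0.7,
                          template_duration_ms = 15, refractory_ms = 20) {
  stopifnot(inherits(n, "neurogram"))
  x <- band_pass(n$samples, n$fs)
  bsel <- seq_along(x) / n$fs > n$baseline_window[1] &
    seq_along(x) / n$fs <= n$baseline_window[2]
  s <- stats::sd(x[bsel])
  if (!is.finite(s) || s == 0) {
    stop("degenerate baseline: zero variance", call. = FALSE)
  }
  w_raw <- triphasic_template(n$fs, template_duration_ms)
  w <- band_pass_template(w_raw, n$fs, trim = TRUE)
  m <- length(w)
  wc <- w - mean(w)
  # running template projection and normalized cross-correlation; windows
  # end at index i (span i-m+1 .. i)
  rollsum <- function(z) {
    cs <- cumsum(z)
    out <- rep(NA_real_, length(z))
    out[m:length(z)] <- cs[m:length(z)] - c(0, cs)[(m:length(z)) - m + 1]
    out
  }
  sxw <- fft_matched(x, wc)
  sx <- rollsum(x)
  sx2 <- rollsum(x^2)
  denom_x <- sqrt(pmax(sx2 - sx^2 / m, 0))
  ncc <- sxw / (denom_x * sqrt(sum(wc^2)))
  amp <- sxw / sum(wc^2) * abs(min(w))  # fitted trough depth
  ncc[!is.finite(ncc)] <- 0
  amp[!is.finite(amp)] <- 0
  ok <- which(amp > threshold_sd * s & ncc >= ncc_threshold)
  if (length(ok) == 0L) {
    return(list(times = numeric(0), amplitudes = numeric(0),
                baseline_sd = s))
  }
  # local maxima of the fitted amplitude among qualifying samples
  refr <- round(refractory_ms / 1000 * n$fs)
  ord <- ok[order(-amp[ok])]
  keep <- logical(length(x))
  taken <- integer(0)
  for (i in ord) {
    if (length(taken) == 0L || all(abs(taken - i) > refr)) {
      keep[i] <- TRUE
      taken <- c(taken, i)
    }
  }
  idx <- sort(which(keep))
  centers <- (idx - (m - 1) / 2) / n$fs  # window ends at idx; center it
  list(times = centers, amplitudes = amp[idx] / s, baseline_sd = s)
}

# FFT cross-correlation: out[i] = sum_j wc[j] * x[i - m + j], i.e. the
# template slid so its window ends at sample i (same alignment as a
# one-sided convolution filter).
fft_matched <- function(x, wc) {
  n <- length(x)
  m <- length(wc)
  nf <- stats::nextn(n + m - 1, 2)
  X <- stats::fft(c(x, numeric(nf - n)))
  W <- stats::fft(c(rev(wc), numeric(nf - m)))
  full <- Re(stats::fft(X * W, inverse = TRUE)) / nf
  out <- rep(NA_real_, n)
  out[m:n] <- full[m:n]
  out
}

# The template is short; filtfilt needs padding, so embed it in zeros.
# `trim` keeps only the contiguous energy-bearing core (|y| above 2% of
# peak) so that matched-filter correlation is not diluted by noise-only
# samples at the template tails.
band_pass_template <- function(w, fs, trim = FALSE) {
  pad <- round(0.05 * fs)
  y <- band_pass(c(numeric(pad), w, numeric(pad)), fs)
  if (!trim) return(y[pad + seq_along(w)])
  keep <- which(abs(y) >= 0.02 * max(abs(y)))
  y[min(keep):max(keep)]
}

#' Synthetic microneurography record
#'
#' Generates a white-noise neurogram with triphasic spikes injected at
#' random times outside a spike-free baseline. Spike size is specified in
#' units of the s.d. of the band-passed baseline, measured in the same
#' (filtered) domain in which the 4.5-s.d. detection rule operates.
#'
#' @param seed Integer seed.
#' @param fs Sampling rate in Hz (default 20000).
#' @param duration Total record length in seconds (default 12).
#' @param baseline Length of the leading spike-free baseline in seconds.
#' @param n_spikes Number of injected spikes (default 10).
#' @param snr Spike trough depth in filtered-baseline s.d. units.
#' @param noise_sd Raw white-noise s.d. (default 1).
#' @param template_duration_ms Template length in ms (default 15).
#' @return A [neurogram()] with attribute `spike_times` (true centers, s).
#' @export
synth_neurogram <- function(seed, fs = 20000, duration = 12, baseline = 4,
                            n_spikes = 10, snr = 6, noise_sd = 1,
                            template_duration_ms = 15) {
  stopifnot(duration > baseline + 1)
  w_raw <- triphasic_template(fs, template_duration_ms)
  m <- length(w_raw)
  n <- round(duration * fs)
  withr::with_seed(as.integer(seed), {
    x <- stats::rnorm(n, 0, noise_sd)
    sd_filt <- stats::sd(band_pass(x, fs)[seq_len(round(baseline * fs))])
    w_filt <- band_pass_template(w_raw, fs)
    scale <- snr * sd_filt / abs(min(w_filt))
    lo <- baseline + 0.25
    hi <- duration - 0.25
    times <- sort(stats::runif(n_spikes, lo, hi))
    while (n_spikes > 1 && any(diff(times) < 0.25)) {
      times <- sort(stats::runif(n_spikes, lo, hi))
    }
    for (tc in times) {
      i0 <- round(tc * fs) - floor(m / 2)
      x[i0 + seq_len(m) - 1L] <- x[i0 + seq_len(m) - 1L] + scale * w_raw
    }
  })
  out <- neurogram(x, fs = fs, baseline_window = c(0, baseline))
  attr(out, "spike_times") <- times
  out
}

#' ADFSCI hypotension-section score
#'
#' The hypotension section of the Autonomic Dysfunction Following Spinal
#' Cord Injury questionnaire has seven items on a five-point scale. The
#' hypotension score is the sum of the seven items; an item is counted as
#' symptomatic when its score is 2 or higher.
#'
#' @param items Integer vector of exactly 7 item scores.
#' @param scale Two-element per-item bounds (default c(0, 4)).
#' @return A list with `score` (sum) and `symptomatic_items` (count of
#'   items >= 2).
#' @examples
#' adfsci_hypotension_score(c(2, 0, 1, 3, 0, 0, 4))  # score 10, 3 items
#' @export
adfsci_hypotension_score <- function(items, scale = c(0, 4)) {
  if (length(items) != 7) {
    stop("the hypotension section has exactly 7 items", call. = FALSE)
  }
  if (any(!is.finite(items)) || any(items != round(items)) ||
      any(items < scale[1]) || any(items > scale[2])) {
    stop("item scores must be integers within [", scale[1], ", ", scale[2],
         "]", call. = FALSE)
  }
  list(score = as.integer(sum(items)),
       symptomatic_items = as.integer(sum(items >= 2)))
}
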