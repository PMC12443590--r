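---
title: "Methods: closed-loop blood-pressure regulation with epidural stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: closed-loop blood-pressure regulation with epidural stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemoloop)
```

## The problem

High spinal cord injury interrupts supraspinal control of the sympathetic
circuits in the lower thoracic spinal cord that constrict the splanchnic
vascular bed. The result is orthostatic hypotension: upon verticalization,
systolic blood pressure (SBP) can fall by 50 mm Hg within three minutes,
far beyond the 20 mm Hg diagnostic criterion, making upright activity
impossible. Epidural electrical stimulation (EES) of the "hemodynamic
hotspot" (the last three thoracic segments) recruits those sympathetic
circuits and raises SBP, with a pressor response that grows approximately
linearly with stimulation amplitude between a response threshold and a
saturation amplitude.

`hemoloop` implements the complete control pipeline around that
physiology: calibration of the amplitude-to-SBP relation, a PID feedback
controller that modulates EES amplitude to hold an SBP target during
orthostatic challenges, comparator controllers (constant-amplitude EES
and a position-based IMU controller), the windowed blood-pressure-change
metrics used to quantify responses, and a set of auxiliary physiological
computations (Doppler flow, impedance volume, sympathetic neurogram spike
detection, symptom scoring, lead-coverage statistics). Because the
clinical data are measurements on implanted participants, the package
ships a synthetic hemodynamic twin so every component can be exercised
and tested end to end at desk scale.

## The synthetic twin

The twin is deliberately minimal: two first-order states riding on a
constant supine baseline,

$$ \mathrm{SBP}(t) = \mathrm{SBP}_0 - D(t) + P(t) + \varepsilon_t, \qquad
   \varepsilon_t \sim N(0, \sigma^2), $$

where the orthostatic drop $D$ relaxes toward
$D_\infty(\theta) = D_{70}\,\sin\theta / \sin 70^\circ$ with time constant
$\tau_D$, and the pressor state $P$ relaxes toward the saturating linear
steady state

$$ P_\infty(a) = g \cdot \min(\max(a - a_{\mathrm{thr}}, 0),
   a_{\mathrm{sat}} - a_{\mathrm{thr}}) $$

with time constant $\tau_P$. States are advanced with the exact
exponential update $x \leftarrow x + (x_\infty - x)(1 - e^{-\Delta t/\tau})$
at $\Delta t = 1$ s, matching the 1 Hz SBP stream of a
finger-plethysmography (Finometer-style) monitor. The exact update (rather
than a forward-Euler step) makes noiseless traces agree with the
closed-form exponential response to machine precision, which the test
suite exploits as an oracle.

Default parameters encode the clinical phenotype:

* `sbp_baseline` 110 mm Hg supine; pulse pressure 40 mm Hg (DBP is a
  derived channel, as is heart rate, which rises by 15 bpm at 70 degrees —
  the clinic reports these but does not model them).
* `orthostatic_drop_70` = 50 mm Hg: the average untreated drop at a
  70-degree tilt. The $\sin\theta$ scaling follows the gravitational
  component of hydrostatic stress; only the 70-degree value is
  clinically anchored.
* `drop_time_constant` = 50 s. The tilt table verticalizes at 2 deg/s
  (70 degrees in 35 s, inside the clinical 45 s bound), and with
  $\tau_D = 50$ s the twin realizes ~96% of the configured drop within
  180 s of tilt onset *including* the table transition, i.e. the "drop
  within 3 min" phenotype. A naive $3\tau = 180$ s choice realizes only
  ~93% once the transition is accounted for.
* `pressor_gain` 5 mm Hg/mA between `amp_threshold` 1 mA and
  `amp_saturation` 12 mA, giving a 55 mm Hg maximal pressor effect —
  enough to counter the worst tilt used here (52 mm Hg at 80 degrees),
  as in responders selected for the therapy.
* `response_time_constant` = 2 s: the neurally mediated pressor onset is
  fast relative to the 1 Hz loop. This also makes the settled second half
  of each 60 s staircase level sit on the configured line to < 1e-6,
  which is what makes exact calibration recovery testable.
* `noise_sd` 2 mm Hg of white Gaussian measurement noise. No baroreflex
  oscillations, Mayer waves, respiratory modulation or autonomic
  dysreflexia events are modeled: passing tests demonstrate correctness
  of the control and measurement pipeline, not robustness to every
  feature of real hemodynamics.
* Tilt tolerance: the clinic ends a tilt at symptom-based presyncope; the
  twin uses an explicit criterion (SBP < 80 mm Hg sustained for 10 s
  while tilted) so tolerance times are computable.

## Protocols

`make_formal_tilt()` builds the clinical orthostatic challenge: supine
baseline, then a single head-up tilt (70 degrees, up to 10 min, reached
in under 45 s). `make_dynamic_tilt()` builds the pseudo-random dynamic
challenge: eight changes of tilt angle spanning 20-80 degrees, each held
60-120 s. Angles are drawn on a 10-degree grid (realistic table
settings), consecutive segments are forced to differ so each entry is a
genuine change, and hold times are continuous uniform; the sequence is a
pure function of its seed. Whether the clinical sequence constrained
ordering or repeats is not documented; the unconstrained grid draw is the
package's choice. `make_staircase()` produces the calibration titration:
amplitude up 1 mA every minute from 0, at 120 Hz / 300 microseconds.

## Calibration

`fit_calibration()` averages SBP over the settled second half of each
staircase level (the first half is discarded to exclude the first-order
transient). The operating range is detected as: minimum = first level
whose mean exceeds the 0 mA mean by `rise_threshold` (default 2 mm Hg,
above 1 Hz noise on a 30-sample mean); maximum = last level still rising
by at least the threshold over its predecessor. Mean SBP is regressed on
amplitude over that range by ordinary least squares. Two boundary rules
matter in practice:

* If the top in-range level rose clearly sub-linearly (increment < 90% of
  the median in-range increment), saturation occurred inside that step;
  the level is kept as the range endpoint but excluded from the
  regression, otherwise a partial step biases the slope by several
  percent.
* With fewer than two in-range levels the fit fails loudly, and a flat
  response raises a "no operating range" error.

`initial_gains()` seeds the controller from the calibration. The
regression slope has units mm Hg/mA while the proportional gain maps a
pressure error (mm Hg) to an amplitude (mA); the slope is therefore
inverted, `kp = 1/slope`. Whether the clinical controller used the slope
or its reciprocal is not documented; inversion is the dimensionally
consistent reading. Integral and derivative gains are expressed as
Ziegler-Nichols-style ratios `ki = kp/Ti`, `kd = kp*Td`. The defaults
(`Ti = 10` s, `Td = 0`) are this package's analogue of the clinical
manual tuning "over one 70-degree tilt": on the default twin they give a
~20 s closed-loop error decay with ample phase margin and no overshoot,
and they regulate the formal tilt into the target range with minutes to
spare. Amplitude bounds are 0 mA to the calibrated maximum.

## The controller

Each control period (1 s, the SBP rate; the 25 ms command latency and
kHz-rate upsampling of the clinical rig are abstracted to "command applied
within one simulator step"):

1. **EWMA smoothing** over a 3 s trailing window with forgetting factor
   0.3. The published phrase admits two readings; the default takes
   0.3 as the per-lag decay (weights $(1-0.3)^k$, newest first),
   window-truncated and normalized. The recursive-update reading
   (weights $0.3\,(1-0.3)^k$) differs only by a constant and yields the
   identical normalized output; the `ewma_mode` switch documents the
   interpretation.
2. **PID with deadband, forgetting and anti-windup.** The error
   `e = target - smoothed SBP` drives
   `u = kp*e + ki*I + kd*de/dt` with `I <- rho*I + e*dt`. The
   ±3 mm Hg deadband is implemented as *hold-with-re-arm*: while idle,
   an error inside the band changes nothing (previous command held,
   integral frozen) so intrinsic variability produces no actuation;
   an excursion beyond the band activates the controller, which then
   corrects until the error has crossed zero inside the band before
   re-arming. Correcting only back to the band edge would leave the
   system parked at the boundary, where the slowly settling orthostatic
   drop repeatedly pushes it marginally outside; correcting to target
   leaves the full half-band as margin. The derivative acts on the
   smoothed error without extra filtering (the EWMA already low-passes;
   `kd` defaults to 0).
3. **Integral forgetting** (`rho`, default 0.999/step at 1 Hz, integral
   half-life ~11.5 min) bounds error accumulation across a session. The
   value matters: the forgetting-capped integral can contribute at most
   `ki*e*dt/(1-rho)`, and with the calibrated gains a 0.995 factor caps
   the command well below the ~11 mA needed to hold the default twin at
   70 degrees — the controller would stall ~6 mm Hg from target.
4. **Anti-windup** (`gamma`, default 0.9/step): when the clipped command
   is unchanged at an amplitude bound, the integral is multiplied by
   `gamma`, so saturation episodes do not accumulate integral that must
   be unwound afterwards. The update order is forgetting, integrate,
   compute, clip, then penalty — the penalty responds to the *emitted*
   saturation.
5. **Ramped output**: commanded changes larger than 0.5 mA are walked in
   0.5 mA steps every 500 ms for participant comfort; a fresh command
   supersedes a ramp in progress. At the 1 Hz sample rate this bounds
   amplitude changes to 1 mA per sample.

`run_continuous()` is the constant-amplitude comparator run through the
same harness. `run_imu_loop()` is the position-based comparator: the
table angle is estimated from a simulated tilt-table accelerometer
(gravity vector plus 0.02 g isotropic noise) via the arccosine of the
normalized dot product with the supine reference axis, mapped through
posture bands (half-open `[low, high)`, last band closed at 90 degrees)
to a banded amplitude, with the same output ramping.

## Metrics

All windows are half-open `[a, b)` over the 1 Hz sample grid, so "before
the start" excludes the start sample. The tilt change compares a 60 s
pre-tilt baseline with a 20 s window "at 3 min", interpreted as centered
on +180 s (`[170, 190)`), the symmetric reading of an ambiguous phrase;
tilts ended early use the final 20 s. Seated stimulation uses 20 s
windows, intraoperative mapping uses 30 s windows (computed as specified,
with a warning, even if a short bout makes them overlap). Postprandial
changes average cuff measures 30-60 min after the meal against the
pre-meal baseline mean. Dynamic-challenge performance is quantified from
1 min before to 1 min after the challenge by the signed mean target
error, the mean absolute error (both are reported, since signedness is
not specified) and the error variability (sample s.d. of the error).
Display smoothing is a centered 10 s moving average with shrinking edge
windows. `time_to_tilt_end()` reports tolerance times with a censoring
indicator for survival-style summaries; the survival modeling itself is
out of scope.

## Auxiliary physiology

* **Doppler flow** (mL/min): $Q = \frac{FV}{2}\cdot\frac{\pi \bar D^2}{4}$
  assuming a parabolic profile, SI inputs, x 6e7 for m^3/s to mL/min.
  Callers pass peak velocity; `velocity_is_mean = TRUE` skips the
  parabolic halving for integrated-envelope mean velocities (the clinic
  describes both; which entered the published equation is not stated).
  Total CBF sums both internal carotids and both vertebrals; the middle
  cerebral arteries are measured but excluded from the sum.
* **Impedance volume**: $V = (L^2 r_{\mathrm{eff}}/R)\cdot 10^6$, with
  $r_{\mathrm{eff}}$ defaulting to 1.0 ohm m. The 1e6 factor suggests mL
  for SI inputs; the units are documented, not asserted.
* **Sympathetic neurogram**: 0.3-2 kHz band-pass (second-order
  Butterworth run forward and backward for zero phase), full-wave
  rectification, 0.1 s leaky integration for the mean-voltage neurogram.
  Spike detection matches a triphasic template (15 ms, lobes
  0.5 : -1 : 0.5, main phase negative, trimmed to its energy-bearing
  core after filtering) against the band-passed signal. The amplitude
  rule — deflection larger than 4.5 x the s.d. of the stimulator-off
  baseline — is applied to the least-squares template-fit trough depth
  rather than a single raw sample: the matched estimate has ~5-fold
  lower noise, so genuine sub-threshold events (3 x SD) are reliably
  rejected and supra-threshold events (6 x SD) reliably kept, which a
  raw-sample rule cannot do at 1 Hz-equivalent error rates. A 0.7
  normalized-correlation gate (calibrated so band-limited noise does not
  erode sensitivity at the amplitude floor, while wrong-polarity or
  wrong-shape deflections fail) and a 20 ms refractory complete the
  detector. All constants are configurable.
* **ADFSCI**: the hypotension score is the sum of the seven hypotension
  items; items scoring >= 2 count as symptomatic. The five-point
  per-item scale is anchored at 0-4 by default and configurable, since
  the anchoring is not published.
* **Lead coverage**: segment lengths are treated as independent normals
  (correlations are unavailable), so the lead length covering a fraction
  $p$ of the population is $\sum\mu + z_p\sqrt{\sum\sigma^2}$ —
  one-sided coverage of the summed length. The package ships synthetic
  segment statistics (labelled as such); the clinical 64.2 mm value
  derives from an unpublished anatomical library and is not reproduced.
  Normalized electrode position is the signed distance from the hotspot
  center over the T9-conus length, rostral positive (one convention,
  documented).

## Numerical and testing choices

Every stochastic function takes an explicit seed and scopes it with
`withr::with_seed`, so identical seeds give byte-identical traces,
fixtures and reports and the global RNG stream is never disturbed.
Problem sizes in the test suite and acceptance script are desk-scale
choices: 20-seed comparator studies on ~15 min challenges, 50-twin
calibration sweeps, 8 s neurograms at 20 kHz with 6 injected spikes,
1e6-draw Monte-Carlo checks of the coverage quantile. Reference
behaviours are checked against independent scalar oracles (explicit
weighted sums, step-by-step PID recurrences, index-enumerated window
means, closed-form exponentials, one-line arithmetic) to 1e-9.

## Worked example

```{r example, eval = FALSE}
twin <- patient_params(noise_sd = 0)
cal <- calibrate_twin(twin, seed = 2)
cal
#> Calibration: operating range [2, 12] mA, SBP = 105.00 + 5.000 * amp (R2 1.000)

cfg <- initial_gains(cal, target = 110)
tilt <- make_formal_tilt(70, 300, 600)

untreated <- simulate_patient(twin, tilt, 0, 900, seed = 1)
bp_change_tilt(untreated, 300, 900)$sbp
#> [1] -48.11142

regulated <- run_closed_loop(twin, tilt, cfg, 900, seed = 1)
max(abs(regulated$sbp[regulated$time >= 600] - 110))
#> [1] 0.5872753
```

## Known limitations

The twin has no baroreflex, no heart-rate feedback, no autonomic
dysreflexia, and white noise only; the controller's advantage over
continuous EES is therefore demonstrated under idealized disturbance
structure. The accelerometer model is a noisy gravity vector, not a full
IMU fusion. Clinical constants that were never published (EWMA reading,
forgetting and penalty factors, spike template geometry, ADFSCI
anchoring) are exposed as configuration with documented defaults rather
than asserted as the clinical values.
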