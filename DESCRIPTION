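Package: hemoloop
Title: Closed-Loop Epidural Stimulation Control of Blood Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for closed-loop regulation of
    systolic blood pressure with epidural electrical stimulation (EES) in
    people with spinal cord injury and orthostatic hypotension. Provides
    tilt-table and stimulation-staircase protocol generators, a synthetic
    hemodynamic digital twin with an angle-dependent orthostatic drop and a
    saturating linear pressor response, calibration of the amplitude-to-SBP
    operating range, a PID controller with EWMA input smoothing, deadband,
    integral forgetting, anti-windup and ramped output, comparator
    controllers (continuous stimulation and IMU position-based), windowed
    blood-pressure change metrics, and auxiliary physiological computations
    (Doppler vessel flow, impedance segment volume, sympathetic neurogram
    processing and spike detection, autonomic-dysfunction symptom scoring,
    and paddle-lead coverage statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
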