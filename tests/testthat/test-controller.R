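test_that("EWMA matches the brute-force weighted sum", {
  expect_equal(ewma_smooth(c(100, 110, 120)),
               (120 + 0.7 * 110 + 0.49 * 100) / (1 + 0.7 + 0.49))
  expect_equal(ewma_smooth(rep(87.3, 10)), 87.3)
  expect_equal(ewma_smooth(123.4), 123.4)
  withr::with_seed(21, {
    for (k in 1:100) {
      x <- rnorm(sample(1:12, 1), 110, 10)
      win <- sample(c(2, 3, 5), 1)
      fg <- runif(1, 0.05, 0.95)
      got <- ewma_smooth(x, window = win, forget = fg)
      expect_equal(got, oracle_ewma(x, win, fg), tolerance = 1e-12)
      expect_gte(got, min(tail(x, win)))
      expect_lte(got, max(tail(x, win)))
    }
  })
  expect_error(ewma_smooth(numeric(0)), "sample")
  # the update-weight reading differs only by normalization
  expect_equal(ewma_smooth(c(1, 5, 9), mode = "update"),
               ewma_smooth(c(1, 5, 9), mode = "decay"))
})

test_that("pid_step follows the documented recurrence on random sequences", {
  withr::with_seed(33, {
    for (k in 1:30) {
      cfg <- controller_config(
        kp = runif(1, 0.05, 1), ki = runif(1, 0, 0.1),
        kd = runif(1, 0, 0.1), target = 110,
        deadband = sample(c(0, 3, 5), 1),
        integral_forget = runif(1, 0.9, 1),
        windup_penalty = runif(1, 0.5, 0.99),
        amp_max = runif(1, 4, 12))
      errors <- rnorm(60, 0, 8)
      st <- controller_state(cfg)
      got <- numeric(length(errors))
      for (i in seq_along(errors)) {
        r <- pid_step(cfg, st, 110 - errors[i], dt = 1)
        st <- r$state
        got[i] <- r$command
      }
      orc <- oracle_pid_run(cfg, errors)
      expect_equal(got, orc$commands, tolerance = 1e-9)
      expect_equal(st$integral, orc$integral, tolerance = 1e-9)
    }
  })
})

test_that("deadband holds the command and pure-P law is linear outside it", {
  cfg <- controller_config(kp = 1, ki = 0, kd = 0, target = 120,
                           amp_max = 20)
  st <- controller_state(cfg, amplitude = 2)
  r <- pid_step(cfg, st, 119, dt = 1)  # |e| = 1 inside the band
  expect_equal(r$command, 2)
  r <- pid_step(cfg, r$state, 122.5, dt = 1)
  expect_equal(r$command, 2)
  # outside: raw u = kp * e = 10 mA
  r <- pid_step(cfg, r$state, 110, dt = 1)
  expect_equal(r$command, 10)
  expect_error(pid_step(cfg, st, NaN, 1), "finite")
})

test_that("windup penalty shrinks the integral while pinned at a bound", {
  cfg <- controller_config(kp = 0, ki = 1, kd = 0, target = 110,
                           deadband = 0, integral_forget = 1,
                           windup_penalty = 0.9, amp_max = 5)
  st <- controller_state(cfg)
  # persistent error of +10 saturates immediately
  ints <- numeric(8)
  for (i in 1:8) {
    r <- pid_step(cfg, st, 100, dt = 1)
    st <- r$state
    ints[i] <- st$integral
    expect_equal(r$command, 5)
  }
  # scalar recurrence: I <- 0.9 * (I + 10) once pinned (first step is not
  # yet "unchanged at the bound", so no penalty there)
  expected <- numeric(8)
  I <- 10  # after first step (command moved 0 -> 5: no penalty)
  expected[1] <- I
  for (i in 2:8) {
    I <- 0.9 * (I + 10)
    expected[i] <- I
  }
  expect_equal(ints, expected, tolerance = 1e-12)
})

test_that("output ramping walks large changes at the configured rate", {
  cfg <- controller_config(kp = 1, target = 110, amp_max = 10)
  st <- controller_state(cfg, amplitude = 2)
  # below the trigger: applied immediately
  r <- ramp_output(cfg, st, 2.4, now = 0)
  expect_equal(r$amplitude, 2.4)
  # large change: 2.0 -> 4.0 takes 4 steps of 0.5 mA spanning 2.0 s
  st <- controller_state(cfg, amplitude = 2)
  emitted <- sapply(0:4, function(k) {
    r <- ramp_output(cfg, st, 4.0, now = k * 0.5)
    st <<- r$state
    r$amplitude
  })
  expect_equal(emitted, c(2.5, 3.0, 3.5, 4.0, 4.0))
  # unchanged command stays unchanged
  r <- ramp_output(cfg, st, 4.0, now = 10)
  expect_equal(r$amplitude, 4.0)
  expect_error(ramp_output(cfg, st, 99, now = 0), "bounds")
})

test_that("closed loop regulates the formal tilt into the deadband", {
  p <- patient_params(noise_sd = 0)
  cfg <- default_calibrated_config()
  prot <- make_formal_tilt(70, 300, 600)
  tr <- run_closed_loop(p, prot, cfg, 900, seed = 1)
  final <- tr[tr$time >= 600, ]
  expect_lte(max(abs(final$sbp - cfg$target)), cfg$deadband)
  # disabled controller equals the continuous run at the initial amplitude
  cfg0 <- controller_config(kp = 0, ki = 0, kd = 0, target = 110,
                            amp_max = 12)
  tr0 <- run_closed_loop(p, prot, cfg0, 600, seed = 2)
  expect_true(all(tr0$amplitude == 0))
  cont0 <- run_continuous(p, prot, 0, 600, seed = 2)
  expect_equal(tr0$sbp, cont0$sbp, tolerance = 1e-12)
  # determinism
  pn <- patient_params(noise_sd = 2)
  a <- run_closed_loop(pn, prot, cfg, 600, seed = 9)
  b <- run_closed_loop(pn, prot, cfg, 600, seed = 9)
  expect_identical(a$sbp, b$sbp)
  expect_identical(a$amplitude, b$amplitude)
})

test_that("continuous stimulation settles at the closed-form level", {
  p <- patient_params(noise_sd = 0)
  prot <- make_formal_tilt(70, 60, 600)
  tr <- run_continuous(p, prot, 12, 660, seed = 1)
  settle <- 110 - orthostatic_setpoint(p, 70) + pressor_steady_state(p, 12)
  expect_equal(tail(tr$sbp, 1), settle, tolerance = 1e-3)
})

test_that("accelerometer angles come from the normalized dot product", {
  expect_equal(angle_from_accel(c(0, 0, 1)), 0)
  expect_equal(angle_from_accel(c(1, 0, 0)), 90)
  expect_equal(angle_from_accel(c(sin(70 * pi / 180), 0,
                                  cos(70 * pi / 180))), 70)
  expect_equal(angle_from_accel(c(0, 0, -2)), 180)
  expect_error(angle_from_accel(c(0, 0, 0)), "zero")
})

test_that("position maps cover [0, 90] with half-open bands", {
  map <- position_map(c(0, 20, 60), c(20, 60, 90),
                      c("supine", "seated", "standing"), c(0, 4, 8))
  expect_equal(map_amplitude(map, 70), 8)
  expect_equal(map_amplitude(map, 0), 0)
  # band edges belong to the upper band; 90 belongs to the last band
  expect_equal(map_amplitude(map, 20), 4)
  expect_equal(map_amplitude(map, 60), 8)
  expect_equal(map_amplitude(map, 90), 8)
  expect_error(map_amplitude(map, 95), "outside")
  expect_error(position_map(c(0, 30), c(20, 90), c("a", "b"), c(0, 1)),
               "contiguous")
})

test_that("IMU loop applies banded amplitudes with ramping", {
  p <- patient_params(noise_sd = 0)
  map <- position_map(c(0, 20, 60), c(20, 60, 90),
                      c("supine", "seated", "standing"), c(0, 4, 8))
  prot <- make_formal_tilt(70, 60, 180)
  tr <- run_imu_loop(p, prot, map, 240, seed = 4)
  expect_equal(tail(tr$amplitude, 1), 8)
  expect_true(all(tr$amplitude %in% seq(0, 8, by = 0.5)))
  expect_true(all(abs(diff(tr$amplitude)) <= 1 + 1e-9))
  # supine protocol stays in the supine band
  flat <- tilt_protocol(0, 120)
  tr0 <- run_imu_loop(p, flat, map, 120, seed = 4)
  expect_true(all(tr0$amplitude == 0))
})

test_that("closed loop beats continuous EES on the dynamic challenge", {
  p <- patient_params()  # noise_sd = 2 default
  cal <- calibrate_twin(patient_params(noise_sd = 0), seed = 99)
  cfg <- initial_gains(cal, target = 110)
  wins <- 0
  for (s in 1:5) {
    prot <- challenge_protocol(s)
    dur <- ceiling(protocol_duration(prot))
    cl <- challenge_errors(run_closed_loop(p, prot, cfg, dur, seed = s),
                           110, 120, dur - 120)
    co <- challenge_errors(run_continuous(p, prot, cal$amp_max, dur,
                                          seed = s + 1000),
                           110, 120, dur - 120)
    wins <- wins + (cl$error_variability < co$error_variability &&
                      cl$target_error_mean_abs < co$target_error_mean_abs)
  }
  expect_equal(wins, 5)
})
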