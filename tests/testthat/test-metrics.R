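make_series <- function(sbp, t0 = 0) {
  n <- length(sbp)
  tt <- seq(t0, t0 + n - 1)
  bp_series(tt, sbp, sbp - 40, rep(70, n), rep(0, n), rep(0, n))
}

test_that("tilt change uses the 60-s baseline and the 20-s window at 3 min", {
  const <- make_series(rep(120, 400))
  expect_equal(bp_change_tilt(const, 100, 380)$sbp, 0)

  # baseline 120, value 70 from tilt onward: change -50
  sbp <- c(rep(120, 100), rep(70, 300))
  ser <- make_series(sbp)
  d <- bp_change_tilt(ser, 100, 380)
  expect_equal(d$sbp, -50)

  # early termination at 150 s: compare window [130, 150) after start
  sbp2 <- c(rep(120, 100), rep(100, 120), rep(60, 30), rep(120, 150))
  ser2 <- make_series(sbp2)
  d2 <- bp_change_tilt(ser2, 100, 250)
  # window [230, 250): samples are all 60
  expect_equal(d2$sbp, 60 - 120)
  expect_error(bp_change_tilt(make_series(rep(1, 50)), 10, 300), "window")
})

test_that("windowed metrics match index-enumeration oracles on random data", {
  withr::with_seed(5, {
    for (k in 1:40) {
      n <- 420
      sbp <- rnorm(n, 110, 15)
      ser <- make_series(sbp)
      d <- bp_change_tilt(ser, 100, 400)
      expect_equal(d$sbp,
                   oracle_window_mean(ser$time, ser$sbp, 270, 290) -
                     oracle_window_mean(ser$time, ser$sbp, 40, 100),
                   tolerance = 1e-9)
      d2 <- bp_change_seated(ser, 60, 300)
      expect_equal(d2$sbp,
                   oracle_window_mean(ser$time, ser$sbp, 230, 250) -
                     oracle_window_mean(ser$time, ser$sbp, 40, 60),
                   tolerance = 1e-9)
      d3 <- bp_change_intraop(ser, 100, 300)
      expect_equal(d3$sbp,
                   oracle_window_mean(ser$time, ser$sbp, 270, 300) -
                     oracle_window_mean(ser$time, ser$sbp, 70, 100),
                   tolerance = 1e-9)
    }
  })
})

test_that("metrics are invariant to shifting the whole record in time", {
  withr::with_seed(9, sbp <- rnorm(420, 105, 12))
  a <- make_series(sbp, t0 = 0)
  b <- make_series(sbp, t0 = 500)
  expect_equal(bp_change_tilt(a, 100, 400)$sbp,
               bp_change_tilt(b, 600, 900)$sbp, tolerance = 1e-12)
  ea <- challenge_errors(a, 110, 100, 300)
  eb <- challenge_errors(b, 110, 600, 800)
  expect_equal(ea$target_error_mean, eb$target_error_mean, tolerance = 1e-12)
  expect_equal(ea$error_variability, eb$error_variability, tolerance = 1e-12)
})

test_that("seated and intraop changes handle steps and short bouts", {
  sbp <- c(rep(110, 100), rep(129, 300))
  ser <- make_series(sbp)
  expect_equal(bp_change_seated(ser, 100, 300)$sbp, 19)
  expect_error(bp_change_seated(ser, 100, 250), "180")
  expect_equal(bp_change_intraop(ser, 100, 350)$sbp, 19)
  expect_warning(bp_change_intraop(ser, 150, 160), "overlap")
})

test_that("postprandial delta averages the 30-60 min cuff window", {
  expect_equal(postprandial_delta(c(110, 112), c(35, 50, 70),
                                  c(95, 99, 130)), -14)
  expect_equal(postprandial_delta(100, 45, 100), 0)
  expect_error(postprandial_delta(c(110), c(10, 70), c(90, 95)),
               "30, 60")
})

test_that("challenge errors report signed mean, |mean| and variability", {
  ser <- make_series(rep(110, 400))
  ce <- challenge_errors(ser, 110, 100, 300)
  expect_equal(ce$target_error_mean, 0)
  expect_equal(ce$error_variability, 0)
  ce5 <- challenge_errors(make_series(rep(115, 400)), 110, 100, 300)
  expect_equal(ce5$target_error_mean, 5)
  expect_equal(ce5$target_error_mean_abs, 5)
  expect_equal(ce5$error_variability, 0)
  alt <- make_series(110 + rep(c(5, -5), 200))
  cea <- challenge_errors(alt, 110, 100, 300)
  expect_equal(cea$target_error_mean, 0, tolerance = 1e-9)
  expect_equal(cea$error_variability,
               sd(rep(c(5, -5), 200)[41:360]), tolerance = 1e-9)
  expect_error(challenge_errors(ser, 110, 30, 300), "cover")
})

test_that("display smoothing is a shrinking centered moving average", {
  ser <- make_series(rep(100, 50))
  expect_equal(smooth_display(ser)$sbp, rep(100, 50))
  imp <- rep(0, 60)
  imp[30] <- 10
  ser2 <- bp_series(0:59, imp + 200, imp + 100, rep(70, 60), rep(0, 60),
                    rep(0, 60))
  sm <- smooth_display(ser2, window = 10)
  expect_equal(sm$sbp[30], 200 + 10 / 10)
  expect_equal(sm$sbp[50], 200)
  expect_equal(smooth_display(ser2, window = 1)$sbp, ser2$sbp)
})

test_that("time to tilt end reports events and censoring", {
  p <- patient_params(noise_sd = 0)
  prot <- make_formal_tilt(70, 60, 600)
  tr <- simulate_patient(p, prot, 0, 660, seed = 1)
  # untreated default twin breaches the 80 mm Hg criterion
  res <- time_to_tilt_end(tr, 60)
  expect_true(res$event)
  expect_equal(res$time, attr(tr, "termination") - 60)
  # explicit criterion scan agrees with the simulator flag
  res2 <- time_to_tilt_end(tr, 60, criterion = list(sbp = 80, hold = 10))
  expect_equal(res2$time, res$time)
  # disabled criterion censors at the record end
  res3 <- time_to_tilt_end(tr, 60, criterion = list())
  expect_false(res3$event)
  expect_equal(res3$time, 600)
  # a trace that never fails is censored
  ok <- run_continuous(p, prot, 12, 660, seed = 1)
  res4 <- time_to_tilt_end(ok, 60)
  expect_false(res4$event)
  expect_error(time_to_tilt_end(tr, 1e4), "outside")
})
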