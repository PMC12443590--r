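test_that("vessel flow matches the parabolic-profile arithmetic oracle", {
  expect_equal(vessel_flow(0.5, 0.005), 294.5243, tolerance = 1e-4)
  expect_equal(vessel_flow(0.3, 0), 0)
  expect_equal(vessel_flow(0, 0.004), 0)
  # quadratic scaling in diameter
  expect_equal(vessel_flow(0.5, 0.01), 4 * vessel_flow(0.5, 0.005))
  # mean-velocity entry point skips the parabolic halving
  expect_equal(vessel_flow(0.5, 0.005, velocity_is_mean = TRUE),
               2 * vessel_flow(0.5, 0.005))
  withr::with_seed(3, {
    v <- runif(100, 0, 1.5)
    d <- runif(100, 0, 0.01)
    expect_equal(vessel_flow(v, d), oracle_flow(v, d), tolerance = 1e-9)
  })
  expect_error(vessel_flow(-1, 0.005), "finite")
})

test_that("total CBF sums the four neck vessels and ignores the MCAs", {
  df <- data.frame(
    vessel = c("ICA_L", "ICA_R", "VA_L", "VA_R", "MCA_L"),
    velocity = c(0.6, 0.55, 0.4, 0.42, 0.9),
    diameter = c(0.005, 0.0048, 0.0035, 0.0034, 0.003))
  expected <- sum(oracle_flow(df$velocity[1:4], df$diameter[1:4]))
  expect_equal(total_cbf(df), expected, tolerance = 1e-9)
  # permutation invariance
  expect_equal(total_cbf(df[sample(nrow(df)), ]), expected,
               tolerance = 1e-9)
  zero <- data.frame(vessel = c("ICA_L", "ICA_R", "VA_L", "VA_R"),
                     velocity = 0, diameter = 0)
  expect_equal(total_cbf(zero), 0)
  expect_error(total_cbf(df[df$vessel != "VA_L", ]), "VA_L")
})

test_that("impedance segment volume follows the geometric formula", {
  expect_equal(segment_volume(0.3, 30), 3000)
  expect_equal(segment_volume(0.3, 60), 1500)  # doubling R halves V
  withr::with_seed(4, {
    L <- runif(1, 0.1, 0.6)
    R <- runif(100, 5, 80)
    expect_equal(segment_volume(L, R), oracle_volume(L, R),
                 tolerance = 1e-9)
    expect_true(all(diff(segment_volume(L, sort(R))) < 0))
  })
  expect_error(segment_volume(0, 30), "length")
  expect_error(segment_volume(0.3, 0), "resistance")
})

test_that("neurogram processing rectifies, integrates and band-limits", {
  fs <- 20000
  zero <- neurogram(rep(0, 2 * fs), fs, c(0, 1))
  expect_true(all(process_neurogram(zero) == 0))

  tt <- seq_len(2 * fs) / fs
  tone1k <- neurogram(sin(2 * pi * 1000 * tt), fs, c(0, 1))
  tone5k <- neurogram(sin(2 * pi * 5000 * tt), fs, c(0, 1))
  r1 <- max(process_neurogram(tone1k))
  r5 <- max(process_neurogram(tone5k))
  expect_gt(20 * log10(r1 / r5), 20)  # >= 20 dB out-of-band attenuation

  withr::with_seed(6, x <- rnorm(2 * fs))
  ng <- neurogram(x + 0.7, fs, c(0, 1))  # DC offset is removed
  y <- process_neurogram(ng)
  expect_true(all(y >= 0))
  rect_peak <- cummax(abs(hemoloop:::band_pass(ng$samples, fs)))
  expect_true(all(y <= rect_peak + 1e-9))
  expect_error(neurogram(rep(0, 100), fs = 20000), "1 s")
  expect_error(neurogram(rep(0, 5000), fs = 3000), "band edge")
})

test_that("spike detection obeys the amplitude rule and morphology gate", {
  sens <- det3 <- numeric(5)
  for (s in 1:5) {
    ng6 <- synth_neurogram(seed = s, duration = 8, baseline = 3,
                           n_spikes = 6, snr = 6)
    det <- detect_spikes(ng6)
    true <- attr(ng6, "spike_times")
    sens[s] <- mean(sapply(true, function(tc)
      any(abs(det$times - tc) < 0.0075)))
    ng3 <- synth_neurogram(seed = s, duration = 8, baseline = 3,
                           n_spikes = 6, snr = 3)
    det3[s] <- length(detect_spikes(ng3)$times)
  }
  expect_gte(mean(sens), 0.95)
  expect_equal(sum(det3), 0)

  # monophasic positive deflections are rejected despite their size
  fs <- 20000
  withr::with_seed(7, {
    x <- rnorm(8 * fs)
    sdf <- sd(hemoloop:::band_pass(x, fs)[1:(3 * fs)])
    lobe <- sin(pi * seq_len(round(0.005 * fs)) / (round(0.005 * fs) + 1))
    for (tc in 4:7) {
      i0 <- round(tc * fs)
      x[i0 + seq_along(lobe)] <- x[i0 + seq_along(lobe)] + 6 * sdf * lobe
    }
  })
  expect_equal(length(detect_spikes(neurogram(x, fs, c(0, 3)))$times), 0)
  # degenerate baseline
  flatng <- neurogram(c(rep(0, 3 * fs), rnorm(fs)), fs, c(0, 2))
  expect_error(detect_spikes(flatng), "degenerate")
})

test_that("ADFSCI hypotension scoring sums items and counts symptoms", {
  expect_equal(adfsci_hypotension_score(rep(0, 7)),
               list(score = 0L, symptomatic_items = 0L))
  expect_equal(adfsci_hypotension_score(c(2, 0, 1, 3, 0, 0, 4)),
               list(score = 10L, symptomatic_items = 3L))
  expect_equal(adfsci_hypotension_score(rep(4, 7)),
               list(score = 28L, symptomatic_items = 7L))
  expect_error(adfsci_hypotension_score(rep(1, 6)), "7 items")
  expect_error(adfsci_hypotension_score(c(rep(0, 6), 9)), "within")
  # packaged example scores
  f <- system.file("extdata", "adfsci_hypotension_synthetic.csv",
                   package = "hemoloop")
  items <- read.csv(f)$score
  res <- adfsci_hypotension_score(items)
  expect_equal(res$score, sum(items))
  expect_equal(res$symptomatic_items, sum(items >= 2))
})
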