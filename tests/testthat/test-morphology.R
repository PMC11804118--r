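test_that("epoch extraction aligns on peaks and drops edge spikes", {
  fs <- 1000
  x <- impulse_signal(seq(0.5, 5, by = 0.5), rep(1, 10), fs, 6)
  ep <- extract_epochs(x, fs, seq(0.5, 5, by = 0.5), half_width = 0.04)
  expect_identical(dim(ep), c(10L, 81L))
  expect_identical(attr(ep, "n_dropped"), 0L)
  expect_true(all(ep[, 41] == 1))  # peak sample centered

  ep2 <- extract_epochs(x, fs, c(0.01, 2), half_width = 0.04)
  expect_identical(nrow(ep2), 1L)
  expect_identical(attr(ep2, "n_dropped"), 1L)

  expect_error(extract_epochs(x, fs, 0.005, half_width = 0.04),
               "coverage error")
  expect_error(extract_epochs(x, fs, numeric(0), 0.04), "coverage error")
})

test_that("epochs around planted noiseless spikes equal the template segment", {
  spec <- synth_spec(duration = 20, noise_sd = 0, amp_jitter_sd = 0, seed = 5)
  sim <- simulate_channel(spec)
  x <- lfp_channel(sim$recording, "ch1")
  ep <- extract_epochs(x, spec$fs, sim$truth$time_s, half_width = 0.04)
  tpl <- spike_template(spec$fs)
  pk <- attr(tpl, "peak_index")
  expected <- c(rep(0, 40 - pk + 1), tpl, rep(0, 40 - (length(tpl) - pk)))
  for (i in seq_len(nrow(ep))) expect_equal(unname(ep[i, ]), expected)
})

test_that("spike averaging is the pointwise mean", {
  one <- matrix(c(0, 1, 0), nrow = 1)
  expect_equal(average_spike(one), c(0, 1, 0))
  x <- matrix(rnorm(20), nrow = 2)
  x[2, ] <- -x[1, ]
  expect_equal(average_spike(x), rep(0, 10))
  expect_error(average_spike(matrix(numeric(0), nrow = 0, ncol = 5)),
               "coverage error")
})

test_that("averaging suppresses noise at the law-of-large-numbers rate", {
  withr::local_seed(8)
  tpl <- c(rep(0, 20), seq(0, 1, length.out = 11), seq(0.95, 0, length.out = 20),
           rep(0, 10))
  sigma <- 0.1
  epochs <- t(replicate(50, tpl + rnorm(length(tpl), 0, sigma)))
  avg <- average_spike(epochs)
  mad_err <- mean(abs(avg - tpl))
  # E|N(0, s/sqrt(50))| = 0.8 * s/sqrt(50); allow wide slack
  expect_lte(mad_err, 2 * sigma / sqrt(50))
})

test_that("slope metrics match the closed form of a triangular spike", {
  fs <- 1000
  # rise 0 -> 1 mV over 10 ms, fall 1 -> 0 over 20 ms, centered in 81 samples
  w <- c(rep(0, 30), seq(0, 1, length.out = 11)[-11], 1,
         seq(1, 0, length.out = 21)[-1], rep(0, 20))
  stopifnot(length(w) == 81, which.max(w) == 41)
  m <- slope_metrics(w, fs)
  expect_equal(m$rising_slope, 100)
  expect_equal(m$descent_slope, -50)
  expect_equal(m$overall_slope, (100 * 10 + 50 * 20) / 30, tolerance = 1e-9)
  expect_equal(m$onset_offset, -0.010)
  expect_equal(m$end_offset, 0.020)

  # symmetric triangle: equal rise and fall
  ws <- c(rep(0, 30), seq(0, 1, length.out = 11)[-11], 1,
          seq(1, 0, length.out = 11)[-1], rep(0, 30))
  ms <- slope_metrics(ws, fs)
  expect_equal(ms$rising_slope, 100)
  expect_equal(ms$descent_slope, -100)
  expect_equal(ms$overall_slope, 100)

  # homogeneity: doubling the waveform doubles every slope
  m2 <- slope_metrics(2 * w, fs)
  expect_equal(m2$rising_slope, 2 * m$rising_slope)
  expect_equal(m2$descent_slope, 2 * m$descent_slope)
  expect_equal(m2$overall_slope, 2 * m$overall_slope)

  # time dilation by k divides slopes by k (same samples, fs/k)
  mk <- slope_metrics(w, fs / 2)
  expect_equal(mk$rising_slope, m$rising_slope / 2)
  expect_equal(mk$descent_slope, m$descent_slope / 2)

  expect_error(slope_metrics(rep(1, 81), fs), "flat waveform")
})

test_that("slopes are signed correctly for any center-peaked waveform", {
  withr::local_seed(77)
  for (i in 1:20) {
    base <- rnorm(40, sd = 0.05)
    w <- c(base, 1 + abs(rnorm(1)), rev(base) * 0.8)
    m <- slope_metrics(w, 500)
    expect_gte(m$rising_slope, 0)
    expect_lte(m$descent_slope, 0)
    expect_gte(m$overall_slope, 0)
    expect_lte(m$onset_offset, 0)
    expect_gte(m$end_offset, 0)
  }
})

test_that("the detect->morph chain recovers the template's analytic slopes", {
  sim <- simulate_channel(synth_spec(duration = 30, seed = 13))
  det <- detect_spikes(sim$recording, "ch1", 40, 0.1, 0.1)
  morph <- spike_morphology(sim$recording, det)
  expect_gte(morph$n_epochs, 10)
  expect_lt(abs(morph$metrics$rising_slope - 100) / 100, 0.05)
  expect_lt(abs(morph$metrics$descent_slope - (-50)) / 50, 0.05)
  expect_identical(nrow(morph$avg_waveform), 81L)
})

test_that("negative-going detections are flipped before averaging", {
  sim <- simulate_channel(synth_spec(duration = 20, seed = 17, noise_sd = 0.02))
  flipped <- lfp_recording(-as.matrix(sim$recording$data),
                           sim$recording$metadata, "ch1")
  det <- detect_spikes(flipped, "ch1", 40, 0.1, 0.1, polarity = "both")
  morph <- spike_morphology(flipped, det)
  expect_identical(morph$n_flipped, morph$n_epochs)
  expect_gt(morph$metrics$rising_slope, 0)
})
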