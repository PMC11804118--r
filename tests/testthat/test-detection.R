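test_that("moving threshold is the stated percentage of the window maximum", {
  # 60% of a 1-mV window maximum -> 0.6 mV
  x <- c(rep(0.2, 1000), c(rep(0.3, 999), 1.0))
  thr <- moving_thresholds(x, fs = 1000, percent = 60)
  expect_equal(thr$threshold_mV, c(0.12, 0.6))
  expect_equal(thr$window_index, 0:1)

  expect_equal(moving_thresholds(x, 1000, percent = 0)$threshold_mV, c(0, 0))
  thr100 <- moving_thresholds(x, 1000, percent = 100)
  expect_equal(thr100$threshold_mV, c(0.2, 1.0))

  # final partial window, rectification of negative deflections
  x2 <- c(rep(0.1, 1000), rep(-2, 500))
  thr2 <- moving_thresholds(x2, 1000, percent = 50)
  expect_equal(thr2$t_end, c(1, 1.5))
  expect_equal(thr2$threshold_mV, c(0.05, 1.0))

  expect_error(moving_thresholds(numeric(0), 1000, 50), "data error")
  expect_error(moving_thresholds(x, 1000, 150), "percent")
})

test_that("subthreshold signals yield zero spikes with undefined stats", {
  rec <- make_recording(ch = rep(0.05, 3000), fs = 1000)
  det <- detect_spikes(rec, "ch", percent = 60, fixed_thr = 0.1,
                       min_dist = 0.1)
  expect_identical(nrow(det$events), 0L)
  s <- glance(det)
  expect_true(all(is.na(c(s$amp_max, s$amp_mean, s$amp_min,
                          s$isi_max, s$isi_mean, s$isi_min))))
  expect_identical(s$firing_rate, 0)
})

test_that("the temporal threshold keeps the larger spike of a close pair", {
  # candidates at 0.00, 0.05, 0.20 s with amplitudes 0.5, 0.8, 0.6 mV:
  # the 0.00 candidate is suppressed by the larger one 0.05 s away
  x <- impulse_signal(c(0, 0.05, 0.20), c(0.5, 0.8, 0.6), 1000, 1)
  rec <- make_recording(ch = x, fs = 1000)
  det <- detect_spikes(rec, "ch", percent = 0, fixed_thr = 0.3,
                       min_dist = 0.1)
  expect_equal(det$events$time_s, c(0.05, 0.20))
  expect_equal(det$events$amplitude_mV, c(0.8, 0.6))
})

test_that("greedy selection equals the enumeration oracle on small instances", {
  withr::local_seed(101)
  for (trial in 1:40) {
    n <- sample(2:10, 1)
    times <- sort(round(runif(n, 0, 1), 3))
    times <- times + seq_len(n) * 1e-4          # avoid exact duplicates
    amps <- round(runif(n, 0.2, 1), 2)
    min_dist <- runif(1, 0.02, 0.3)
    keep <- epilfp:::.greedy_refractory(times, amps, min_dist)
    expect_equal(sort(times[keep]), brute_refractory(times, amps, min_dist),
                 info = paste("trial", trial))
  }
})

test_that("raising any threshold never increases the spike count", {
  sim <- simulate_channel(synth_spec(duration = 30, seed = 9))
  count <- function(percent = 40, fixed = 0.1, dist = 0.1) {
    nrow(detect_spikes(sim$recording, "ch1", percent, fixed, dist)$events)
  }
  for (grid in list(
    sapply(c(10, 30, 50, 70, 90), function(p) count(percent = p)),
    sapply(c(0.05, 0.1, 0.3, 0.6, 1.2), function(f) count(fixed = f)),
    sapply(c(0.05, 0.1, 0.5, 1, 3), function(d) count(dist = d))
  )) {
    expect_true(all(diff(grid) <= 0))
  }
})

test_that("every event clears its window's effective threshold and the refractory gap", {
  for (seed in 1:12) {
    spec <- synth_spec(duration = 10, spike_rate = 1.2, seed = seed,
                       amp_jitter_sd = 0.3)
    sim <- simulate_channel(spec)
    det <- detect_spikes(sim$recording, "ch1", percent = 35,
                         fixed_thr = 0.08, min_dist = 0.15)
    if (nrow(det$events) >= 2) {
      expect_true(all(diff(det$events$time_s) >= 0.15))
    }
    eff <- pmax(det$thresholds$threshold_mV[
      match(det$events$window_index, det$thresholds$window_index)], 0.08)
    expect_true(all(det$events$amplitude_mV >= eff))
  }
})

test_that("analysis spans are honored and windows anchor at t_start", {
  x <- impulse_signal(c(0.5, 2.5, 4.5), c(1, 1, 1), 1000, 5)
  rec <- make_recording(ch = x, fs = 1000)
  det <- detect_spikes(rec, "ch", 0, 0.5, 0.1, t_start = 2, t_end = 4)
  expect_equal(det$events$time_s, 2.5)
  expect_equal(det$thresholds$t_start, c(2, 3))
  expect_equal(det$summary$firing_rate, 0.5)
  expect_error(detect_spikes(rec, "ch", 0, 0.5, 0.1, t_end = 9),
               "range error")
  expect_error(detect_spikes(rec, "nope", 0, 0.5, 0.1), "lookup error")
})

test_that("detection summary matches hand-computed statistics", {
  ev <- tibble::tibble(time_s = c(1, 2, 4), amplitude_mV = c(0.5, 1, 0.75))
  s <- detection_summary(ev, 0, 10)
  expect_equal(s$n_spikes, 3L)
  expect_equal(c(s$amp_max, s$amp_mean, s$amp_min), c(1, 0.75, 0.5))
  expect_equal(c(s$isi_max, s$isi_mean, s$isi_min), c(2, 1.5, 1))
  expect_equal(s$firing_rate, 0.3)

  one <- detection_summary(ev[2, ], 0, 5)
  expect_true(all(is.na(c(one$isi_max, one$isi_mean, one$isi_min))))
  expect_equal(one$firing_rate, 0.2)

  expect_error(detection_summary(ev, 5, 5), "range error")
})

test_that("planted spikes are recovered on synthetic data", {
  sim <- simulate_channel(synth_spec(duration = 30, seed = 21))
  det <- detect_spikes(sim$recording, "ch1", percent = 40, fixed_thr = 0.1,
                       min_dist = 0.1)
  sc <- score_detection(sim$truth$time_s, det$events$time_s, tol = 0.01)
  expect_gte(sc$f1, 0.95)
})

test_that("negative-going spikes are found under both and negative polarity", {
  sim <- simulate_channel(synth_spec(duration = 20, seed = 31, noise_sd = 0.02))
  flipped <- lfp_recording(-as.matrix(sim$recording$data),
                           sim$recording$metadata, "ch1")
  for (pol in c("both", "negative")) {
    det <- detect_spikes(flipped, "ch1", 40, 0.1, 0.1, polarity = pol)
    sc <- score_detection(sim$truth$time_s, det$events$time_s, tol = 0.01)
    expect_gte(sc$recall, 0.95)
  }
  # positive polarity must not see them
  det_pos <- detect_spikes(flipped, "ch1", 40, 0.3, 0.1, polarity = "positive")
  expect_lt(nrow(det_pos$events),
            nrow(sim$truth) / 2)
})
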