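test_that("spike template is the specified sharp transient", {
  tpl <- spike_template(1000, rise_ms = 10, fall_ms = 20, amp = 1)
  expect_length(tpl, 31)
  expect_equal(max(tpl), 1)
  expect_identical(which.max(tpl), 11L)  # peak at 10 ms
  expect_identical(attr(tpl, "peak_index"), 11L)
  expect_equal(tpl[1], 0)
  expect_equal(tpl[31], 0)

  expect_equal(as.numeric(spike_template(1000, amp = 0)), rep(0, 31))
  expect_error(spike_template(1000, rise_ms = 0), "parameter error")
  expect_warning(spike_template(1000, rise_ms = 5, fall_ms = 5), "20-80 ms")

  sw <- spike_template(1000, slow_wave = list(amp = 0.2, duration = 0.1))
  expect_length(sw, 31 + 100)
  expect_equal(max(sw[32:131]), 0.2, tolerance = 1e-3)
})

test_that("template slopes feed the morphology closed form", {
  tpl <- spike_template(1000)
  w <- c(rep(0, 30), tpl, rep(0, 20))  # 81 samples, peak centered
  expect_identical(which.max(w), 41L)
  m <- slope_metrics(w, 1000)
  expect_equal(m$rising_slope, 100)
  expect_equal(m$descent_slope, -50)
})

test_that("noiseless simulation is exactly the sum of placed templates", {
  spec <- synth_spec(duration = 15, noise_sd = 0, amp_jitter_sd = 0, seed = 2)
  sim <- simulate_channel(spec)
  x <- lfp_channel(sim$recording, "ch1")
  tpl <- spike_template(spec$fs)
  pk <- attr(tpl, "peak_index")
  y <- numeric(length(x))
  for (t in sim$truth$time_s) {
    c0 <- round(t * spec$fs) + 1L
    idx <- (c0 - pk + 1L):(c0 - pk + length(tpl))
    y[idx] <- y[idx] + tpl
  }
  expect_equal(x, y)
})

test_that("simulation is bit-identical under a fixed seed", {
  spec <- synth_spec(duration = 10, seed = 33)
  a <- simulate_channel(spec)
  b <- simulate_channel(spec)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth, b$truth)
  c <- simulate_channel(synth_spec(duration = 10, seed = 34))
  expect_false(identical(a$recording$data, c$recording$data))

  p1 <- simulate_pair(spec)
  p2 <- simulate_pair(spec)
  expect_identical(p1$reference$data, p2$reference$data)
  expect_identical(p1$comparison$data, p2$comparison$data)
})

test_that("spike counts concentrate around the Poisson expectation", {
  sim <- simulate_channel(synth_spec(duration = 60, spike_rate = 0.5, seed = 7))
  expect_lt(abs(nrow(sim$truth) - 30), 3 * sqrt(30))
})

test_that("planted trains respect the placement gap and recording bounds", {
  for (seed in 1:10) {
    spec <- synth_spec(duration = 20, spike_rate = 2, seed = seed)
    sim <- simulate_channel(spec)
    tt <- sim$truth$time_s
    expect_true(all(tt >= 0 & tt < spec$duration))
    if (length(tt) >= 2) expect_true(all(diff(tt) >= spec$refractory - 1e-9))
  }
  expect_error(synth_spec(spike_rate = 10), "infeasible")
})

test_that("pair simulation honors the coincidence probability extremes", {
  all_spec <- synth_spec(duration = 30, coincidence_p = 1, time_jitter_sd = 0,
                         seed = 4)
  pair <- simulate_pair(all_spec)
  tr <- pair$truth
  expect_true(all(tr$reference$coincident))
  expect_equal(tr$reference$comp_time, tr$reference$time_s)
  expect_true(all(tr$reference$time_s %in% tr$comparison$time_s))

  none <- simulate_pair(synth_spec(duration = 30, coincidence_p = 0, seed = 4))
  expect_false(any(none$truth$reference$coincident))
  expect_true(all(is.na(none$truth$reference$comp_time)))
})

test_that("the flagged fraction matches the planted coincidence probability", {
  pair <- simulate_pair(synth_spec(duration = 400, coincidence_p = 0.6,
                                   seed = 6))
  frac <- mean(pair$truth$reference$coincident)
  n <- nrow(pair$truth$reference)
  expect_lt(abs(frac - 0.6), 3 * sqrt(0.6 * 0.4 / n))
})

test_that("detection scoring counts matches within tolerance", {
  expect_equal(score_detection(c(1, 2, 3), c(1, 2, 3), 0.01)[
    , c("precision", "recall", "f1")],
    tibble::tibble(precision = 1, recall = 1, f1 = 1))

  s <- score_detection(c(1, 2, 3), numeric(0), 0.01)
  expect_true(is.na(s$precision))
  expect_identical(s$recall, 0)
  expect_identical(s$f1, 0)

  s2 <- score_detection(c(1, 2, 3), c(1.005, 2.5), tol = 0.01)
  expect_equal(s2$precision, 0.5)
  expect_equal(s2$recall, 1 / 3)
  expect_equal(s2$f1, 0.4)
})
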