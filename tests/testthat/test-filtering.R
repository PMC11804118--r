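test_that("bandpass design validates its band edges", {
  expect_error(design_bandpass("fir", 1000, low = 200, high = 100),
               "parameter error")
  expect_error(design_bandpass("fir", 1000, low = 0, high = 100),
               "parameter error")
  expect_error(design_bandpass("iir", 150, low = 10, high = 100), "Nyquist")
  expect_error(design_bandpass("fir", 1000, order_or_taps = 100),
               "odd")
})

test_that("default FIR design is an odd-length 10-100 Hz bandpass", {
  spec <- design_bandpass("fir", fs = 1000)
  expect_identical(spec$kind, "fir")
  expect_equal(c(spec$low, spec$high), c(10, 100))
  expect_identical(spec$numtaps %% 2L, 1L)
  expect_gte(spec$numtaps, 1000)
  # linear phase: symmetric impulse response
  expect_equal(spec$b, rev(spec$b), tolerance = 1e-12)
})

test_that("Butterworth IIR design is stable with the expected response", {
  spec <- design_bandpass("iir", fs = 1000, order_or_taps = 4)
  poles <- polyroot(rev(spec$a))
  expect_true(all(Mod(poles) < 1))
  resp <- filter_response(spec, c(1, 50))
  expect_gte(resp$magnitude[resp$freq_hz == 50], 0.95)
  expect_lte(resp$magnitude[resp$freq_hz == 1], 0.05)
})

test_that("zero-phase filtering preserves passband sinusoids in place", {
  fs <- 1000
  t <- (0:(5 * fs - 1)) / fs
  interior <- seq(fs, 4 * fs)   # central 3 s, away from edges
  for (kind in c("fir", "iir")) {
    spec <- design_bandpass(kind, fs)
    s50 <- sin(2 * pi * 50 * t)
    y <- apply_zero_phase(s50, spec)
    expect_length(y, length(s50))
    gain50 <- sqrt(mean(y[interior]^2) / mean(s50[interior]^2))
    expect_gte(gain50, 0.9)
    # peaks unshifted (+-1 sample): compare one interior peak location
    pk_in <- interior[1] - 1 + which.max(s50[interior])
    near <- (pk_in - 10):(pk_in + 10)
    pk_out <- near[which.max(y[near])]
    expect_lte(abs(pk_out - pk_in), 1)

    s1 <- sin(2 * pi * 1 * t)
    y1 <- apply_zero_phase(s1, spec)
    expect_lte(sqrt(mean(y1[interior]^2) / mean(s1[interior]^2)), 0.1)
  }
})

test_that("all-zero input stays all-zero and short signals error", {
  spec <- design_bandpass("iir", 1000)
  expect_equal(apply_zero_phase(numeric(1000), spec), numeric(1000))
  expect_error(apply_zero_phase(numeric(30), spec), "length error")
})

test_that("zero-phase filtering is linear", {
  set.seed(42)
  spec <- design_bandpass("iir", 500)
  x <- rnorm(2000)
  y <- rnorm(2000)
  lhs <- apply_zero_phase(2 * x - 3 * y, spec)
  rhs <- 2 * apply_zero_phase(x, spec) - 3 * apply_zero_phase(y, spec)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("two-pass magnitude equals the single-pass magnitude squared", {
  fs <- 1000
  t <- (0:(8 * fs - 1)) / fs
  interior <- seq(2 * fs, 6 * fs)
  for (kind in c("fir", "iir")) {
    spec <- design_bandpass(kind, fs)
    for (f in c(5, 20, 50, 120)) {
      s <- sin(2 * pi * f * t)
      y <- apply_zero_phase(s, spec)
      measured <- sqrt(mean(y[interior]^2) / mean(s[interior]^2))
      h1 <- filter_response(spec, f)$magnitude
      expect_equal(measured, h1^2, tolerance = 0.02)
    }
  }
})

test_that("symmetric pulses keep their extremum at the same sample", {
  fs <- 1000
  k <- 2500L
  x <- numeric(5 * fs)
  x[(k - 25):(k + 25)] <- 1 - abs(-25:25) / 25   # symmetric triangle at k
  for (kind in c("fir", "iir")) {
    y <- apply_zero_phase(x, design_bandpass(kind, fs))
    expect_lte(abs(which.max(y) - k), 1)
  }
})

test_that("filter_recording caps the default FIR length on short recordings", {
  rec <- make_recording(ch = rnorm(2000), fs = 1000)
  expect_warning(out <- filter_recording(rec, "fir"), "capped")
  expect_true(out$metadata$filtered)
  expect_identical(nrow(out$data), 2000L)
  spec <- attr(out, "filter_spec")
  expect_lte(spec$numtaps, 500)
})
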