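#' Extract peak-aligned spike epochs from a signal
#'
#' Cuts one window of `2 * half_width` seconds around each spike peak,
#' aligned on the peak sample. Spikes whose full window does not fit inside
#' the signal are dropped and counted.
#'
#' @param x Numeric voltage series in mV.
#' @param fs Sampling frequency in Hz.
#' @param spike_times Spike peak times in seconds (relative to the start of
#'   `x`), non-empty.
#' @param half_width Epoch half-extent around each peak in seconds (default
#'   0.04 s, matching the upper bound of the 20--80 ms epileptiform-spike
#'   duration definition).
#' @return A numeric matrix, one row per usable spike and
#'   `2 * round(half_width * fs) + 1` columns, with attribute `n_dropped`
#'   (edge-excluded spikes) and `offset_s` (per-column time offsets from the
#'   peak).
#' @export
extract_epochs <- function(x, fs, spike_times, half_width = 0.04) {
  if (!length(spike_times)) stop("coverage error: no spike times supplied", call. = FALSE)
  if (half_width <= 0) stop("parameter error: half_width must be > 0", call. = FALSE)
  hw <- as.integer(round(half_width * fs))
  centers <- as.integer(round(spike_times * fs)) + 1L
  ok <- centers - hw >= 1L & centers + hw <= length(x)
  if (!any(ok)) {
    stop("coverage error: no spike has a complete window inside the signal",
         call. = FALSE)
  }
  epochs <- t(vapply(centers[ok],
                     function(c) x[(c - hw):(c + hw)],
                     numeric(2L * hw + 1L)))
  attr(epochs, "n_dropped") <- sum(!ok)
  attr(epochs, "offset_s") <- (-hw:hw) / fs
  epochs
}

#' Representative average epileptiform spike
#'
#' Pointwise arithmetic mean across peak-aligned epochs.
#'
#' @param epochs An epoch matrix from [extract_epochs()] (rows = spikes).
#' @return A numeric vector of the same width, carrying over the `offset_s`
#'   attribute when present.
#' @export
average_spike <- function(epochs) {
  if (is.null(dim(epochs)) || nrow(epochs) < 1L) {
    stop("coverage error: need at least one epoch", call. = FALSE)
  }
  avg <- colMeans(epochs)
  attr(avg, "offset_s") <- attr(epochs, "offset_s")
  avg
}

#' Slope metrics of an averaged spike waveform
#'
#' Computes the three average slope measures of the representative spike:
#' the rising segment (onset to peak), the descent segment (peak to descent
#' end, negative for a falling segment), and the overall spike (mean absolute
#' per-sample slope over the onset-to-end support).
#'
#' The rising onset is the last local minimum of the waveform before the
#' central peak and the descent end the first local minimum after it, falling
#' back to the window edges when none exists. Local minima are found with a
#' slope tolerance: scanning outward from the peak, the segment continues
#' while the per-sample slope exceeds `rel_tol * max(|diff(waveform)|)`, so
#' small residual-noise wiggles on an averaged waveform do not truncate or
#' extend the segments. With `rel_tol = 0` the rule is the exact
#' local-minimum rule.
#'
#' @param avg_waveform Numeric waveform (mV) whose central sample is the
#'   spike peak, as produced by [average_spike()].
#' @param fs Sampling frequency in Hz.
#' @param rel_tol Slope tolerance as a fraction of the waveform's maximum
#'   absolute per-sample slope (default 0.05).
#' @return A one-row tibble: `rising_slope`, `descent_slope`,
#'   `overall_slope` (mV/s), `onset_offset` (s, <= 0), `end_offset` (s, >= 0).
#' @examples
#' # 1-mV triangle at fs 1000: 10 ms rise, 20 ms fall, in an 81-sample window
#' w <- c(rep(0, 30), seq(0, 1, length.out = 11), seq(0.95, 0, length.out = 20),
#'        rep(0, 20))
#' slope_metrics(w, fs = 1000)  # rising 100, descent -50 mV/s
#' @export
slope_metrics <- function(avg_waveform, fs, rel_tol = 0.05) {
  w <- as.numeric(avg_waveform)
  n <- length(w)
  if (n < 3L || n %% 2L == 0L) {
    stop("morphology error: waveform must have odd length >= 3", call. = FALSE)
  }
  ctr <- (n + 1L) %/% 2L
  d <- diff(w)
  if (max(abs(d)) == 0) {
    stop("morphology error: flat waveform, no identifiable peak", call. = FALSE)
  }
  if (w[ctr] < max(w)) {
    stop("morphology error: central sample is not the waveform maximum; align epochs on the peak",
         call. = FALSE)
  }
  tol <- rel_tol * max(abs(d))
  # onset: walk left from the peak while the waveform keeps rising toward it
  onset <- 1L
  for (i in (ctr - 1L):1L) {
    if (d[i] <= tol) { onset <- i + 1L; break }
    if (i == 1L) onset <- 1L
  }
  # descent end: walk right while the waveform keeps falling
  end <- n
  for (j in ctr:(n - 1L)) {
    if (d[j] >= -tol) { end <- j; break }
  }
  dt <- 1 / fs
  rising <- if (onset < ctr) (w[ctr] - w[onset]) / ((ctr - onset) * dt) else NA_real_
  descent <- if (end > ctr) (w[end] - w[ctr]) / ((end - ctr) * dt) else NA_real_
  overall <- if (end > onset) mean(abs(d[onset:(end - 1L)])) / dt else NA_real_
  tibble::tibble(
    rising_slope = rising,
    descent_slope = descent,
    overall_slope = overall,
    onset_offset = (onset - ctr) * dt,
    end_offset = (end - ctr) * dt
  )
}

#' Morphology of the average detected spike
#'
#' Runs the full morphology analysis on a detection result: extracts
#' peak-aligned epochs around every detected spike, averages them into the
#' representative epileptiform spike, and computes the three slope metrics.
#' Negative-going events (epochs whose central value is negative) are
#' sign-flipped before averaging so mixed-polarity detections do not cancel;
#' the reported waveform is then positive-peaked.
#'
#' @param recording The [lfp_recording()] the detection was run on.
#' @param detection A `spike_detection` from [detect_spikes()] (or a numeric
#'   vector of spike times in seconds).
#' @param channel Channel label; defaults to the detection's channel.
#' @param half_width Epoch half-extent in seconds (default 0.04).
#' @param rel_tol Slope tolerance passed to [slope_metrics()].
#' @return A `spike_morphology` object: `avg_waveform` (tibble `offset_s`,
#'   `mV`), `n_epochs`, `n_dropped`, `metrics` (one-row tibble), `half_width`.
#'   [tidy()] returns the waveform, [glance()] the metrics.
#' @export
spike_morphology <- function(recording, detection, channel = NULL,
                             half_width = 0.04, rel_tol = 0.05) {
  stopifnot(inherits(recording, "lfp_recording"))
  if (inherits(detection, "spike_detection")) {
    times <- detection$events$time_s
    if (is.null(channel)) channel <- detection$channel
  } else {
    times <- as.numeric(detection)
    if (is.null(channel)) stop("`channel` is required when `detection` is a time vector",
                               call. = FALSE)
  }
  if (!length(times)) stop("coverage error: detection contains no spikes", call. = FALSE)
  fs <- recording$metadata$fs
  x <- lfp_channel(recording, channel)
  epochs <- extract_epochs(x, fs, times, half_width)
  ctr <- (ncol(epochs) + 1L) %/% 2L
  flip <- sign(epochs[, ctr])
  flip[flip == 0] <- 1
  epochs_aligned <- epochs * flip
  avg <- colMeans(epochs_aligned)
  metrics <- slope_metrics(avg, fs, rel_tol)
  structure(
    list(
      avg_waveform = tibble::tibble(offset_s = attr(epochs, "offset_s"),
                                    mV = as.numeric(avg)),
      n_epochs = nrow(epochs),
      n_dropped = attr(epochs, "n_dropped"),
      n_flipped = sum(flip < 0),
      metrics = metrics,
      half_width = half_width,
      channel = channel,
      metadata = recording$metadata
    ),
    class = "spike_morphology"
  )
}

#' @export
print.spike_morphology <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<spike_morphology> channel '%s', %d epoch(s) averaged (%d edge-dropped)\n",
              x$channel, x$n_epochs, x$n_dropped))
  cat(sprintf("  rising %.2f mV/s, descent %.2f mV/s, overall %.2f mV/s\n",
              m$rising_slope, m$descent_slope, m$overall_slope))
  cat(sprintf("  support: %.1f ms before to %.1f ms after the peak\n",
              -1000 * m$onset_offset, 1000 * m$end_offset))
  invisible(x)
}

#' @method tidy spike_morphology
#' @export
tidy.spike_morphology <- function(x, ...) x$avg_waveform

#' @method glance spike_morphology
#' @export
glance.spike_morphology <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(n_epochs = x$n_epochs,
                                  n_dropped = x$n_dropped),
                   x$metrics)
}
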