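#' Per-window moving amplitude thresholds
#'
#' Partitions a signal into contiguous, non-overlapping analysis windows of
#' `win_len` seconds (the final window may be shorter) and sets each window's
#' detection threshold to `percent`% of the maximum rectified amplitude
#' observed inside it. Recomputing the threshold per window copes with the
#' considerable amplitude variation of epileptiform spikes along a recording:
#' with `percent = 60` and a window whose maximum amplitude is 1 mV, that
#' window's threshold is 0.6 mV.
#'
#' @param x Numeric voltage series in mV.
#' @param fs Sampling frequency in Hz.
#' @param percent Moving-threshold percentage, in \[0, 100\].
#' @param win_len Window length in seconds (default 1).
#' @param polarity How amplitude is rectified before taking the window
#'   maximum: `"both"` (absolute value, the default), `"positive"` (signal as
#'   is), or `"negative"` (sign-flipped signal).
#'
#' @return A tibble with one row per window: `window_index` (0-based),
#'   `t_start`, `t_end` (s, relative to the start of `x`) and `threshold_mV`.
#' @examples
#' moving_thresholds(c(rep(0.2, 1000), rep(1, 1000)), fs = 1000, percent = 60)
#' @export
moving_thresholds <- function(x, fs, percent, win_len = 1,
                              polarity = c("both", "positive", "negative")) {
  polarity <- match.arg(polarity)
  if (length(x) == 0) stop("data error: empty signal", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("parameter error: fs must be > 0", call. = FALSE)
  if (!is.numeric(percent) || percent < 0 || percent > 100) {
    stop("parameter error: percent must be in [0, 100]", call. = FALSE)
  }
  if (win_len <= 0) stop("parameter error: win_len must be > 0", call. = FALSE)
  r <- .rectify(x, polarity)
  tt <- (seq_along(x) - 1) / fs
  w <- floor(tt / win_len)
  mx <- tapply(r, w, max)
  idx <- as.integer(names(mx))
  tibble::tibble(
    window_index = idx,
    t_start = idx * win_len,
    t_end = pmin((idx + 1) * win_len, length(x) / fs),
    threshold_mV = as.numeric(mx) * percent / 100
  )
}

.rectify <- function(x, polarity) {
  switch(polarity, both = abs(x), positive = x, negative = -x)
}

#' Detect epileptiform spikes with three thresholds
#'
#' Automatic epileptiform spike detection combining (1) a moving amplitude
#' threshold recomputed per analysis window as a percentage of that window's
#' maximum rectified amplitude, (2) a fixed amplitude floor guaranteeing a
#' minimum acceptable spike amplitude, and (3) a temporal (refractory)
#' threshold: a minimum allowed distance between consecutive accepted spikes,
#' preventing polyphasic complexes from being counted as separate events.
#'
#' Candidate events are maximal runs of consecutive samples whose rectified
#' value reaches the per-sample effective threshold
#' `max(window moving threshold, fixed_thr)`, each reduced to its extremum
#' sample. The temporal threshold is then enforced by greedy selection in
#' descending amplitude order (ties broken toward the earlier time): a
#' candidate is kept iff no already-kept spike lies within `min_dist` of it,
#' so a polyphasic complex is counted once, at its dominant deflection.
#' Analysis windows are anchored at `t_start`.
#'
#' @param recording An [lfp_recording()].
#' @param channel Channel label or index.
#' @param percent Moving-threshold percentage in \[0, 100\].
#' @param fixed_thr Fixed amplitude floor in mV (>= 0).
#' @param min_dist Minimum inter-spike distance in seconds (> 0).
#' @param win_len Analysis-window length in seconds (default 1).
#' @param polarity `"both"` (default), `"positive"` or `"negative"`.
#' @param t_start,t_end Analysis span in seconds (half-open
#'   `[t_start, t_end)`); `t_end` defaults to the recording duration.
#'
#' @return A `spike_detection` object with elements `events` (tibble:
#'   `time_s`, `amplitude_mV`, `sample_index` 0-based, `window_index`),
#'   `thresholds` (per-window tibble), `params`, `summary` (see
#'   [detection_summary()]), `channel` and `metadata`. Use [tidy()] for the
#'   event table and [glance()] for the one-row summary.
#' @examples
#' sim <- simulate_channel(synth_spec(duration = 10, seed = 1))
#' det <- detect_spikes(sim$recording, "ch1",
#'                      percent = 40, fixed_thr = 0.1, min_dist = 0.1)
#' glance(det)
#' @export
detect_spikes <- function(recording, channel, percent, fixed_thr, min_dist,
                          win_len = 1,
                          polarity = c("both", "positive", "negative"),
                          t_start = 0, t_end = NULL) {
  stopifnot(inherits(recording, "lfp_recording"))
  polarity <- match.arg(polarity)
  fs <- recording$metadata$fs
  dur <- lfp_duration(recording)
  if (is.null(t_end)) t_end <- dur
  if (t_end <= t_start) stop("range error: t_end must exceed t_start", call. = FALSE)
  if (t_end > dur + 1e-9) {
    stop(sprintf("range error: t_end (%g s) exceeds recording duration (%g s)",
                 t_end, dur), call. = FALSE)
  }
  if (fixed_thr < 0) stop("parameter error: fixed_thr must be >= 0", call. = FALSE)
  if (min_dist <= 0) stop("parameter error: min_dist must be > 0", call. = FALSE)
  if (is.numeric(channel)) channel <- recording$channel_labels[channel]
  x_full <- lfp_channel(recording, channel)

  # half-open span [t_start, t_end): samples with t_start <= (i-1)/fs < t_end
  i0 <- floor(t_start * fs + 1e-9) + 1L
  i1 <- ceiling(t_end * fs - 1e-9)
  x <- x_full[i0:i1]
  thr <- moving_thresholds(x, fs, percent, win_len, polarity)
  thr$t_start <- thr$t_start + t_start
  thr$t_end <- thr$t_end + t_start

  r <- .rectify(x, polarity)
  tt <- t_start + (seq_along(x) - 1) / fs
  w <- floor((tt - t_start) / win_len)
  eff <- pmax(thr$threshold_mV[match(w, thr$window_index)], fixed_thr)
  above <- r >= eff

  cand <- .candidate_peaks(r, above)
  if (nrow(cand)) {
    cand$time_s <- tt[cand$i]
    cand$sample_index <- (i0 - 1L) + cand$i - 1L  # 0-based, recording origin
    cand$window_index <- w[cand$i]
    keep <- .greedy_refractory(cand$time_s, cand$amp, min_dist)
    events <- cand[keep, c("time_s", "amp", "sample_index", "window_index")]
    names(events)[2] <- "amplitude_mV"
    events <- events[order(events$time_s), , drop = FALSE]
  } else {
    events <- tibble::tibble(time_s = numeric(), amplitude_mV = numeric(),
                             sample_index = integer(), window_index = integer())
  }
  events <- tibble::as_tibble(events)
  params <- list(percent = percent, fixed_thr = fixed_thr, min_dist = min_dist,
                 win_len = win_len, polarity = polarity,
                 t_start = t_start, t_end = t_end)
  structure(
    list(events = events, thresholds = thr, params = params,
         summary = detection_summary(events, t_start, t_end),
         channel = channel, metadata = recording$metadata),
    class = "spike_detection"
  )
}

# maximal runs of suprathreshold samples, each reduced to its extremum
# (ties -> earliest sample)
.candidate_peaks <- function(r, above) {
  if (!any(above)) return(tibble::tibble(i = integer(), amp = numeric()))
  rl <- rle(above)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  runs <- which(rl$values)
  i <- integer(length(runs)); amp <- numeric(length(runs))
  for (k in seq_along(runs)) {
    s <- starts[runs[k]]; e <- ends[runs[k]]
    j <- s + which.max(r[s:e]) - 1L
    i[k] <- j; amp[k] <- r[j]
  }
  tibble::tibble(i = i, amp = amp)
}

# greedy temporal-threshold enforcement: visit candidates in descending
# amplitude (ties -> earlier time); keep one iff no kept spike is closer
# than min_dist
.greedy_refractory <- function(times, amps, min_dist) {
  ord <- order(-amps, times)
  kept_t <- numeric(0)
  keep <- logical(length(times))
  for (j in ord) {
    if (!length(kept_t) || all(abs(kept_t - times[j]) >= min_dist)) {
      keep[j] <- TRUE
      kept_t <- c(kept_t, times[j])
    }
  }
  keep
}

#' Summary statistics of a detected spike train
#'
#' Reports, over the analyzed span, the spike count, the maximum, average and
#' minimum spike amplitude, the maximum, average and minimum inter-spike
#' interval, and the firing rate (spikes per second of analyzed span).
#' With fewer than 2 events the ISI statistics are undefined and with 0
#' events the amplitude statistics are undefined; undefined values are
#' reported as `NA`, never as 0.
#'
#' @param events A tibble with columns `time_s` and `amplitude_mV`,
#'   time-sorted (as produced by [detect_spikes()]).
#' @param t_start,t_end Analyzed span in seconds, `t_end > t_start`.
#' @return A one-row tibble: `n_spikes`, `amp_max`, `amp_mean`, `amp_min`
#'   (mV), `isi_max`, `isi_mean`, `isi_min` (s), `firing_rate` (spikes/s).
#' @examples
#' ev <- tibble::tibble(time_s = c(1, 2, 4), amplitude_mV = c(0.5, 1, 0.75))
#' detection_summary(ev, 0, 10)
#' @export
detection_summary <- function(events, t_start, t_end) {
  if (t_end <= t_start) stop("range error: t_end must exceed t_start", call. = FALSE)
  n <- nrow(events)
  amps <- events$amplitude_mV
  isi <- if (n >= 2) diff(events$time_s) else numeric(0)
  tibble::tibble(
    n_spikes = n,
    amp_max = if (n >= 1) max(amps) else NA_real_,
    amp_mean = if (n >= 1) mean(amps) else NA_real_,
    amp_min = if (n >= 1) min(amps) else NA_real_,
    isi_max = if (n >= 2) max(isi) else NA_real_,
    isi_mean = if (n >= 2) mean(isi) else NA_real_,
    isi_min = if (n >= 2) min(isi) else NA_real_,
    firing_rate = n / (t_end - t_start)
  )
}

#' @export
print.spike_detection <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<spike_detection> channel '%s', span [%g, %g) s\n",
              x$channel, x$params$t_start, x$params$t_end))
  cat(sprintf("  thresholds: moving %g%% / fixed %g mV / refractory %g s\n",
              x$params$percent, x$params$fixed_thr, x$params$min_dist))
  cat(sprintf("  %d spike(s), rate %.3f /s", s$n_spikes, s$firing_rate))
  if (s$n_spikes > 0) {
    cat(sprintf(", amplitude %.3f [%.3f, %.3f] mV",
                s$amp_mean, s$amp_min, s$amp_max))
  }
  cat("\n")
  invisible(x)
}

#' @method tidy spike_detection
#' @export
tidy.spike_detection <- function(x, ...) x$events

#' @method glance spike_detection
#' @export
glance.spike_detection <- function(x, ...) x$summary
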