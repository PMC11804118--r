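#' Specification of a synthetic LFP recording
#'
#' Collects the parameters of the synthetic LFP generator. The defaults
#' describe the validation conditions used throughout the package: a 60-s
#' recording at 1 kHz with ~30 planted 1-mV epileptiform spikes
#' (Poisson rate 0.5/s) riding on band-limited baseline noise generated as
#' white Gaussian noise of SD 0.05 mV low-pass shaped below 30 Hz, and, for
#' two-channel simulations, a 60% chance that each reference spike recurs on
#' the comparison channel with 10 ms Gaussian timing jitter.
#'
#' @param fs Sampling frequency in Hz.
#' @param duration Recording length in seconds.
#' @param noise_sd SD of the white Gaussian noise (mV) before low-pass
#'   shaping; SNR is defined as `amp / noise_sd`.
#' @param spike_rate Spike rate in spikes/s (Poisson, thinned by a refractory
#'   gap of template width + 20 ms so planted spikes stay individually
#'   resolvable).
#' @param amp Template peak amplitude in mV.
#' @param amp_jitter_sd SD of per-spike amplitude jitter in mV.
#' @param rise_ms,fall_ms Template rise/fall durations in ms (defaults 10 and
#'   20, inside the 20--80 ms epileptiform-spike duration definition).
#' @param slow_wave Optional trailing slow wave: `list(amp = , duration = )`
#'   in mV and seconds, or `NULL` for none.
#' @param coincidence_p Probability that a reference spike recurs on the
#'   comparison channel (pair simulations), in \[0, 1\].
#' @param time_jitter_sd SD of the timing jitter of recurring spikes, in s.
#' @param min_gap Minimum gap between planted spikes, in s. The effective
#'   placement gap is `max(min_gap, template width + 0.02)`; the default
#'   0.12 s keeps planted spikes individually resolvable by a detector using
#'   the standard 0.1-s temporal threshold, with margin for the +-10 ms
#'   ground-truth matching tolerance.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `synth_spec` object (validated named list).
#' @export
synth_spec <- function(fs = 1000, duration = 60, noise_sd = 0.05,
                       spike_rate = 0.5, amp = 1, amp_jitter_sd = 0.1,
                       rise_ms = 10, fall_ms = 20, slow_wave = NULL,
                       coincidence_p = 0.6, time_jitter_sd = 0.01,
                       min_gap = 0.12, seed = 1L) {
  num_ok <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  if (!num_ok(fs) || fs <= 0) stop("parameter error: fs must be > 0", call. = FALSE)
  if (!num_ok(duration) || duration <= 0) {
    stop("parameter error: duration must be > 0", call. = FALSE)
  }
  for (nm in c("noise_sd", "spike_rate", "amp", "amp_jitter_sd",
               "time_jitter_sd")) {
    v <- get(nm)
    if (!num_ok(v) || v < 0) {
      stop(sprintf("parameter error: %s must be >= 0", nm), call. = FALSE)
    }
  }
  if (!num_ok(rise_ms) || rise_ms <= 0 || !num_ok(fall_ms) || fall_ms <= 0) {
    stop("parameter error: rise_ms and fall_ms must be > 0", call. = FALSE)
  }
  if (!num_ok(coincidence_p) || coincidence_p < 0 || coincidence_p > 1) {
    stop("parameter error: coincidence_p must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(slow_wave) &&
      !(is.list(slow_wave) && all(c("amp", "duration") %in% names(slow_wave)))) {
    stop("parameter error: slow_wave must be NULL or list(amp=, duration=)",
         call. = FALSE)
  }
  if (!num_ok(min_gap) || min_gap < 0) {
    stop("parameter error: min_gap must be >= 0", call. = FALSE)
  }
  refractory <- max(min_gap,
                    (rise_ms + fall_ms) / 1000 +
                      (if (!is.null(slow_wave)) slow_wave$duration else 0) + 0.02)
  if (spike_rate * refractory > 0.8) {
    stop("parameter error: spike_rate is infeasible for the template's refractory gap",
         call. = FALSE)
  }
  structure(
    list(fs = fs, duration = duration, noise_sd = noise_sd,
         spike_rate = spike_rate, amp = amp, amp_jitter_sd = amp_jitter_sd,
         rise_ms = rise_ms, fall_ms = fall_ms, slow_wave = slow_wave,
         coincidence_p = coincidence_p, time_jitter_sd = time_jitter_sd,
         min_gap = min_gap, seed = as.integer(seed), refractory = refractory),
    class = "synth_spec"
  )
}

#' Piecewise-linear epileptiform spike template
#'
#' A sharp transient rising linearly from 0 to `amp` over `rise_ms` and
#' falling back to 0 over `fall_ms` (asymmetric by default, peak value
#' exactly `amp`), optionally followed by a low-amplitude half-sine slow
#' wave. A warning is issued when the sharp component falls outside the
#' 20--80 ms epileptiform-spike duration definition.
#'
#' @inheritParams synth_spec
#' @return A numeric waveform (mV) with attribute `peak_index` (1-based).
#' @examples
#' tpl <- spike_template(1000)  # 30 ms triangle, peak 1 mV at 10 ms
#' max(tpl)
#' @export
spike_template <- function(fs, rise_ms = 10, fall_ms = 20, amp = 1,
                           slow_wave = NULL) {
  if (rise_ms <= 0 || fall_ms <= 0) {
    stop("parameter error: rise_ms and fall_ms must be > 0", call. = FALSE)
  }
  total <- rise_ms + fall_ms
  if (total < 20 || total > 80) {
    warning(sprintf("template duration %g ms is outside the 20-80 ms spike definition",
                    total))
  }
  nr <- max(1L, as.integer(round(rise_ms / 1000 * fs)))
  nf <- max(1L, as.integer(round(fall_ms / 1000 * fs)))
  w <- c(seq(0, amp, length.out = nr + 1L),
         seq(amp, 0, length.out = nf + 1L)[-1])
  if (!is.null(slow_wave) && slow_wave$amp != 0 && slow_wave$duration > 0) {
    nsw <- max(1L, as.integer(round(slow_wave$duration * fs)))
    w <- c(w, slow_wave$amp * sin(pi * seq_len(nsw) / nsw))
  }
  attr(w, "peak_index") <- nr + 1L
  w
}

# Poisson spike times on [margin, duration - margin_end], thinned to keep
# consecutive gaps >= refractory
.poisson_times <- function(rate, duration, refractory, t_min, t_max) {
  if (rate <= 0 || t_max <= t_min) return(numeric(0))
  times <- numeric(0)
  t <- t_min
  last <- -Inf
  repeat {
    t <- t + stats::rexp(1, rate)
    if (t > t_max) break
    if (t - last >= refractory) {
      times <- c(times, t)
      last <- t
    }
  }
  times
}

.shape_noise <- function(n, fs, noise_sd) {
  noise <- stats::rnorm(n, 0, noise_sd)
  if (noise_sd > 0 && fs / 2 > 30) {
    bt <- signal::butter(4, 30 / (fs / 2), type = "low")
    noise <- as.numeric(signal::filter(bt$b, bt$a, noise))
  }
  noise
}

# add template * (a / template peak amp) at each peak time; times must leave
# room for the full template
.place_spikes <- function(x, fs, tpl, times, amps, tpl_amp) {
  pk <- attr(tpl, "peak_index")
  for (k in seq_along(times)) {
    c0 <- as.integer(round(times[k] * fs)) + 1L
    idx <- (c0 - pk + 1L):(c0 - pk + length(tpl))
    x[idx] <- x[idx] + tpl * (amps[k] / tpl_amp)
  }
  x
}

.synth_metadata <- function(spec, n_channels = 1L, animal_id = "SIM") {
  lfp_metadata("synthetic", animal_id, fs = spec$fs,
               researcher = "simulator", n_channels = n_channels, gain = 1)
}

#' Simulate a single-channel LFP recording with planted spikes
#'
#' Baseline noise is white Gaussian noise (SD `noise_sd`) low-pass shaped
#' below 30 Hz (not renormalized; the shaped baseline has a smaller SD).
#' Spike times are drawn from a Poisson process of rate `spike_rate`,
#' thinned to enforce a refractory gap of template width + 20 ms, and a
#' spike template with per-spike amplitude jitter is added at each time.
#' Identical seeds give identical output.
#'
#' @param spec A [synth_spec()].
#' @param animal_id Animal identifier written into the metadata.
#' @return A list: `recording` (an [lfp_recording()], channel `"ch1"`) and
#'   `truth` (tibble `time_s`, `amp_mV` of the planted spikes).
#' @examples
#' sim <- simulate_channel(synth_spec(duration = 5, seed = 42))
#' nrow(sim$truth)
#' @export
simulate_channel <- function(spec, animal_id = "SIM") {
  stopifnot(inherits(spec, "synth_spec"))
  withr::with_seed(spec$seed, {
    tpl <- spike_template(spec$fs, spec$rise_ms, spec$fall_ms, spec$amp,
                          spec$slow_wave)
    pk <- attr(tpl, "peak_index")
    n <- as.integer(round(spec$duration * spec$fs))
    t_min <- pk / spec$fs
    t_max <- spec$duration - (length(tpl) - pk + 1L) / spec$fs
    times <- .poisson_times(spec$spike_rate, spec$duration, spec$refractory,
                            t_min, t_max)
    times <- round(times * spec$fs) / spec$fs  # snap to the sample grid
    amps <- pmax(spec$amp + stats::rnorm(length(times), 0, spec$amp_jitter_sd),
                 0.1 * spec$amp)
    x <- .shape_noise(n, spec$fs, spec$noise_sd)
    x <- .place_spikes(x, spec$fs, tpl, times, amps, spec$amp)
    rec <- lfp_recording(matrix(x, ncol = 1, dimnames = list(NULL, "ch1")),
                         .synth_metadata(spec, 1L, animal_id))
    list(recording = rec,
         truth = tibble::tibble(time_s = times, amp_mV = amps))
  })
}

#' Simulate a reference/comparison channel pair with known coincidence
#'
#' The reference channel is generated as in [simulate_channel()]. Each
#' reference spike recurs on the comparison channel with probability
#' `coincidence_p`, at its time plus `Normal(0, time_jitter_sd)` jitter;
#' independent comparison-only spikes are added at rate
#' `spike_rate * (1 - coincidence_p)`. The comparison train is thinned to the
#' same refractory gap (recurring spikes lost to thinning or edge clipping
#' have their coincidence flag cleared).
#'
#' @inheritParams simulate_channel
#' @return A list: `reference` and `comparison` (single-channel
#'   [lfp_recording()]s) and `truth`, itself a list of tibbles — `reference`
#'   (`time_s`, `amp_mV`, `coincident`, `comp_time`) and `comparison`
#'   (`time_s`, `amp_mV`, `from_ref`).
#' @export
simulate_pair <- function(spec, animal_id = "SIM") {
  stopifnot(inherits(spec, "synth_spec"))
  withr::with_seed(spec$seed, {
    tpl <- spike_template(spec$fs, spec$rise_ms, spec$fall_ms, spec$amp,
                          spec$slow_wave)
    pk <- attr(tpl, "peak_index")
    n <- as.integer(round(spec$duration * spec$fs))
    t_min <- pk / spec$fs
    t_max <- spec$duration - (length(tpl) - pk + 1L) / spec$fs
    snap <- function(t) round(t * spec$fs) / spec$fs

    ref_times <- snap(.poisson_times(spec$spike_rate, spec$duration,
                                     spec$refractory, t_min, t_max))
    k <- length(ref_times)
    ref_amps <- pmax(spec$amp + stats::rnorm(k, 0, spec$amp_jitter_sd),
                     0.1 * spec$amp)

    recurs <- stats::runif(k) < spec$coincidence_p
    comp_time_of_ref <- rep(NA_real_, k)
    comp_time_of_ref[recurs] <-
      snap(ref_times[recurs] + stats::rnorm(sum(recurs), 0, spec$time_jitter_sd))
    # recurring spikes clipped out of the placeable span are lost
    lost <- recurs & (comp_time_of_ref < t_min | comp_time_of_ref > t_max)
    comp_time_of_ref[lost] <- NA_real_

    indep <- snap(.poisson_times(spec$spike_rate * (1 - spec$coincidence_p),
                                 spec$duration, spec$refractory, t_min, t_max))
    comp <- tibble::tibble(
      time_s = c(comp_time_of_ref[!is.na(comp_time_of_ref)], indep),
      from_ref = c(which(!is.na(comp_time_of_ref)),
                   rep(NA_integer_, length(indep)))
    )
    comp <- comp[order(comp$time_s), ]
    # refractory thinning on the merged comparison train
    keep <- logical(nrow(comp))
    last <- -Inf
    for (i in seq_len(nrow(comp))) {
      if (comp$time_s[i] - last >= spec$refractory) {
        keep[i] <- TRUE
        last <- comp$time_s[i]
      }
    }
    comp <- comp[keep, ]
    comp$amp_mV <- pmax(spec$amp + stats::rnorm(nrow(comp), 0, spec$amp_jitter_sd),
                        0.1 * spec$amp)

    coincident <- logical(k)
    comp_time <- rep(NA_real_, k)
    surv <- comp$from_ref[!is.na(comp$from_ref)]
    coincident[surv] <- TRUE
    comp_time[surv] <- comp$time_s[match(surv, comp$from_ref)]

    x_ref <- .place_spikes(.shape_noise(n, spec$fs, spec$noise_sd),
                           spec$fs, tpl, ref_times, ref_amps, spec$amp)
    x_comp <- .place_spikes(.shape_noise(n, spec$fs, spec$noise_sd),
                            spec$fs, tpl, comp$time_s, comp$amp_mV, spec$amp)
    md <- .synth_metadata(spec, 1L, animal_id)
    list(
      reference = lfp_recording(matrix(x_ref, ncol = 1,
                                       dimnames = list(NULL, "ref")), md),
      comparison = lfp_recording(matrix(x_comp, ncol = 1,
                                        dimnames = list(NULL, "comp")), md),
      truth = list(
        reference = tibble::tibble(time_s = ref_times, amp_mV = ref_amps,
                                   coincident = coincident,
                                   comp_time = comp_time),
        comparison = tibble::tibble(time_s = comp$time_s, amp_mV = comp$amp_mV,
                                    from_ref = comp$from_ref)
      )
    )
  })
}

#' Score a detection against planted ground truth
#'
#' One-to-one matching of detected to true spike times within a tolerance
#' (greedy by ascending `|dt|`, the same rule as [match_events()]), reported
#' as precision (`matches / n_detected`), recall (`matches / n_true`) and
#' their harmonic mean F1. The precision of an empty detection is undefined
#' (`NA`), its recall 0.
#'
#' @param true_times,detected_times Sorted spike times in seconds.
#' @param tol Matching tolerance in seconds (> 0).
#' @return A one-row tibble: `n_true`, `n_detected`, `n_matched`,
#'   `precision`, `recall`, `f1`.
#' @examples
#' score_detection(c(1, 2, 3), c(1.005, 2.5), tol = 0.01)
#' @export
score_detection <- function(true_times, detected_times, tol) {
  if (tol <= 0) stop("parameter error: tol must be > 0", call. = FALSE)
  n_true <- length(true_times)
  n_det <- length(detected_times)
  m <- if (n_true && n_det) nrow(match_events(true_times, detected_times, tol)) else 0L
  precision <- if (n_det > 0) m / n_det else NA_real_
  recall <- if (n_true > 0) m / n_true else NA_real_
  f1 <- if (n_true == 0 && n_det == 0) {
    NA_real_
  } else if (m == 0) {
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  tibble::tibble(n_true = n_true, n_detected = n_det, n_matched = m,
                 precision = precision, recall = recall, f1 = f1)
}
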