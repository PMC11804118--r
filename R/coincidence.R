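#' Match spike events between two channels
#'
#' One-to-one greedy matching by ascending absolute time difference (ties
#' broken toward the earlier reference time, then the earlier comparison
#' time): a pair is admitted iff `|ref_time - comp_time| <= window` and
#' neither member is already matched. One-to-one matching prevents a dense
#' comparison train from certifying several reference spikes with a single
#' event.
#'
#' @param ref_times,comp_times Time-sorted spike times in seconds.
#' @param window Maximum `|dt|` for a match, in seconds (> 0).
#' @return A tibble with columns `ref_time`, `comp_time`, `dt`
#'   (`comp_time - ref_time`), one row per matched pair, sorted by `ref_time`.
#' @examples
#' match_events(c(1, 2, 3), c(1.04, 2.5), window = 0.1)
#' @export
match_events <- function(ref_times, comp_times, window) {
  if (!is.numeric(window) || window <= 0) {
    stop("parameter error: window must be > 0", call. = FALSE)
  }
  empty <- tibble::tibble(ref_time = numeric(), comp_time = numeric(),
                          dt = numeric())
  if (!length(ref_times) || !length(comp_times)) return(empty)
  # candidate pairs within the window
  cand <- expand.grid(i = seq_along(ref_times), j = seq_along(comp_times))
  cand$dt <- comp_times[cand$j] - ref_times[cand$i]
  cand <- cand[abs(cand$dt) <= window, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand <- cand[order(abs(cand$dt), ref_times[cand$i], comp_times[cand$j]), ,
               drop = FALSE]
  used_i <- logical(length(ref_times))
  used_j <- logical(length(comp_times))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used_i[i] && !used_j[j]) {
      keep[k] <- TRUE
      used_i[i] <- TRUE
      used_j[j] <- TRUE
    }
  }
  m <- cand[keep, , drop = FALSE]
  out <- tibble::tibble(ref_time = ref_times[m$i], comp_time = comp_times[m$j],
                        dt = m$dt)
  out[order(out$ref_time), ]
}

#' Ictal spike coincidence between two channels
#'
#' Quantifies how often epileptiform spikes co-occur on two neural
#' substrates: one channel is designated the reference and the other the
#' comparison channel, and a reference spike is coincident when a comparison
#' spike falls within `window` seconds of it (symmetric window, matched
#' one-to-one via [match_events()]). The headline percentage is
#' `100 * n_matched / n_ref`; because "per analyzed period" is an equally
#' natural normalization, the coincident-event rate per second of analyzed
#' span is reported alongside it.
#'
#' @param ref,comp `spike_detection` objects (or numeric spike-time vectors
#'   in seconds) for the reference and comparison channels.
#' @param window Maximum `|dt|` for a coincidence, in seconds.
#' @param t_start,t_end Analysis span in seconds; events are filtered to
#'   `[t_start, t_end)`. Defaults cover the detections' own spans (or the
#'   full extent of supplied time vectors).
#' @return A `spike_coincidence` object: `pairs` (tibble), `n_ref`, `n_comp`,
#'   `n_matched`, `percent`, `rate_per_s`, `window`, `t_start`, `t_end`.
#'   [tidy()] returns the pairs, [glance()] the one-row summary. An error is
#'   raised when the span contains no reference spikes (the percentage is
#'   undefined, not 0).
#' @examples
#' spike_coincidence(c(1, 2, 3), c(1.04, 2.5), window = 0.1,
#'                   t_start = 0, t_end = 4)
#' @export
spike_coincidence <- function(ref, comp, window,
                              t_start = NULL, t_end = NULL) {
  get_times <- function(x) {
    if (inherits(x, "spike_detection")) x$events$time_s else sort(as.numeric(x))
  }
  get_span <- function(x) {
    if (inherits(x, "spike_detection")) c(x$params$t_start, x$params$t_end)
    else c(0, if (length(x)) max(as.numeric(x)) + window else window)
  }
  ref_t <- get_times(ref)
  comp_t <- get_times(comp)
  if (is.null(t_start)) t_start <- min(get_span(ref)[1], get_span(comp)[1])
  if (is.null(t_end)) t_end <- max(get_span(ref)[2], get_span(comp)[2])
  if (t_end <= t_start) stop("range error: t_end must exceed t_start", call. = FALSE)
  ref_t <- ref_t[ref_t >= t_start & ref_t < t_end]
  comp_t <- comp_t[comp_t >= t_start & comp_t < t_end]
  if (!length(ref_t)) {
    stop("undefined-percentage error: no reference spikes in the analyzed span",
         call. = FALSE)
  }
  pairs <- match_events(ref_t, comp_t, window)
  md <- if (inherits(ref, "spike_detection")) ref$metadata else NULL
  structure(
    list(pairs = pairs,
         n_ref = length(ref_t), n_comp = length(comp_t),
         n_matched = nrow(pairs),
         percent = 100 * nrow(pairs) / length(ref_t),
         rate_per_s = nrow(pairs) / (t_end - t_start),
         window = window, t_start = t_start, t_end = t_end,
         ref_times = ref_t, comp_times = comp_t,
         metadata = md),
    class = "spike_coincidence"
  )
}

#' @export
print.spike_coincidence <- function(x, ...) {
  cat(sprintf("<spike_coincidence> window %g s, span [%g, %g) s\n",
              x$window, x$t_start, x$t_end))
  cat(sprintf("  %d / %d reference spikes coincident = %.2f%% (%.4f matches/s; %d comparison spikes)\n",
              x$n_matched, x$n_ref, x$percent, x$rate_per_s, x$n_comp))
  invisible(x)
}

#' @method tidy spike_coincidence
#' @export
tidy.spike_coincidence <- function(x, ...) x$pairs

#' @method glance spike_coincidence
#' @export
glance.spike_coincidence <- function(x, ...) {
  tibble::tibble(n_ref = x$n_ref, n_comp = x$n_comp, n_matched = x$n_matched,
                 percent = x$percent, rate_per_s = x$rate_per_s,
                 window = x$window, t_start = x$t_start, t_end = x$t_end)
}
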