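# shared fixtures and independent oracles

make_metadata <- function(n_channels = 1L, fs = 1000, gain = 1,
                          animal = "R01") {
  lfp_metadata("unit-test", animal, fs = fs, gain = gain,
               n_channels = n_channels)
}

make_recording <- function(..., fs = 1000) {
  cols <- list(...)
  lfp_recording(as.data.frame(cols), make_metadata(length(cols), fs = fs),
                names(cols))
}

# a signal of isolated single-sample impulses on a zero baseline
impulse_signal <- function(times, amps, fs, duration) {
  x <- numeric(round(duration * fs))
  x[round(times * fs) + 1L] <- amps
  x
}

# Enumeration oracle for the temporal threshold: all conflict-free subsets
# (pairwise gaps >= min_dist), choosing the one the priority order
# (descending amplitude, ties earlier time) prefers lexicographically.
brute_refractory <- function(times, amps, min_dist) {
  n <- length(times)
  pri <- order(-amps, times)           # candidate indices by priority
  rank_of <- integer(n); rank_of[pri] <- seq_len(n)
  feasible <- function(idx) {
    if (length(idx) < 2) return(TRUE)
    all(abs(outer(times[idx], times[idx], "-"))[lower.tri(diag(length(idx)))] >=
          min_dist)
  }
  best <- NULL
  best_key <- NULL
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!feasible(idx)) next
    key <- sort(rank_of[idx])
    # lexicographic preference: earlier priority ranks first; a longer set
    # wins on a prefix tie (greedy keeps every compatible candidate)
    if (is.null(best)) {
      best <- idx; best_key <- key
    } else {
      l <- max(length(key), length(best_key))
      a <- c(key, rep(Inf, l - length(key)))
      b <- c(best_key, rep(Inf, l - length(best_key)))
      cmp <- which(a != b)
      if (length(cmp) && a[cmp[1]] < b[cmp[1]]) {
        best <- idx; best_key <- key
      }
    }
  }
  sort(times[best])
}

# recursive maximum-cardinality matching oracle for event coincidence
brute_max_matching <- function(ref, comp, window) {
  n <- length(ref); m <- length(comp)
  if (!n || !m) return(0L)
  rec <- function(i, used) {
    if (i > n) return(0L)
    best <- rec(i + 1L, used)  # leave ref i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && abs(ref[i] - comp[j]) <= window) {
        used[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1L, logical(m))
}

# literal two-pass evaluation of the Pearson formula, loop-based
brute_pearson <- function(a, b) {
  n <- length(a)
  ma <- 0; mb <- 0
  for (i in seq_len(n)) { ma <- ma + a[i] / n; mb <- mb + b[i] / n }
  sa <- 0; sb <- 0; cov <- 0
  for (i in seq_len(n)) {
    sa <- sa + (a[i] - ma)^2
    sb <- sb + (b[i] - mb)^2
    cov <- cov + (a[i] - ma) * (b[i] - mb)
  }
  cov / ((n - 1) * sqrt(sa / (n - 1)) * sqrt(sb / (n - 1)))
}

# Minimal EDF writer, built directly from the format definition (fixed-width
# ASCII header, 256 bytes + 256 per signal; int16 little-endian records).
# Independent of the package's reader.
write_edf <- function(path, channels, fs, phys_min = -5, phys_max = 5) {
  ns <- length(channels)
  n_per_rec <- fs                      # 1-second records
  n_rec <- length(channels[[1]]) %/% n_per_rec
  pad <- function(s, w) formatC(as.character(s), width = -w)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("patient", 80), pad("recording", 80),
                pad("01.01.24", 8), pad("00.00.00", 8),
                pad(256 * (1 + ns), 8), pad("", 44),
                pad(n_rec, 8), pad(1, 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  wf <- function(vals, w) writeChar(paste0(sapply(vals, pad, w = w),
                                           collapse = ""), con, eos = NULL)
  wf(names(channels), 16)
  wf(rep("", ns), 80)                  # transducer
  wf(rep("mV", ns), 8)                 # physical dimension
  wf(rep(phys_min, ns), 8)
  wf(rep(phys_max, ns), 8)
  wf(rep(-32768, ns), 8)
  wf(rep(32767, ns), 8)
  wf(rep("", ns), 80)                  # prefiltering
  wf(rep(n_per_rec, ns), 8)
  wf(rep("", ns), 32)
  scale <- (phys_max - phys_min) / (32767 - (-32768))
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      seg <- channels[[s]][((r - 1) * n_per_rec + 1):(r * n_per_rec)]
      dig <- as.integer(round((seg - phys_min) / scale)) - 32768L
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
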