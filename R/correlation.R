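#' Pearson correlation with its defining components
#'
#' Computes the Pearson coefficient of two equal-length voltage series from
#' its defining formula,
#' `r = sum((a - mean(a)) * (b - mean(b))) / ((n - 1) * sd(a) * sd(b))`,
#' with sample (n-1) standard deviations, and returns the components
#' alongside the coefficient. The scale runs from -1 (inverse correlation)
#' through 0 (no linear interdependence) to 1 (direct correlation).
#'
#' @param a,b Numeric series of equal length >= 2, finite.
#' @return A one-row tibble: `n`, `mean_a`, `mean_b`, `sd_a`, `sd_b`, `r`.
#' @examples
#' pearson_components(c(1, 2, 3), c(1, 3, 2))  # r = 0.5
#' @export
pearson_components <- function(a, b) {
  if (length(a) != length(b)) {
    stop("shape error: series lengths differ", call. = FALSE)
  }
  n <- length(a)
  if (n < 2) stop("shape error: need at least 2 samples", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("data error: series must be finite", call. = FALSE)
  }
  ma <- sum(a) / n
  mb <- sum(b) / n
  sa <- sqrt(sum((a - ma)^2) / (n - 1))
  sb <- sqrt(sum((b - mb)^2) / (n - 1))
  if (sa == 0 || sb == 0) {
    stop("undefined-correlation error: zero variance in one series", call. = FALSE)
  }
  r <- sum((a - ma) * (b - mb)) / ((n - 1) * sa * sb)
  tibble::tibble(n = n, mean_a = ma, mean_b = mb, sd_a = sa, sd_b = sb, r = r)
}

#' Correlation-coefficient matrix across all channels
#'
#' Pearson correlation between every pair of channels over a chosen span,
#' as a symmetric k x k matrix with unit diagonal. Undefined entries (a
#' zero-variance channel) are flagged as `NA`, never silently zeroed.
#'
#' @param recording An [lfp_recording()] with at least 2 channels.
#' @param t_start,t_end Analysis span in seconds (half-open); `t_end`
#'   defaults to the recording duration.
#' @return An `lfp_correlation` object wrapping the matrix (`$matrix`) with
#'   the span and metadata. [tidy()] returns the long channel-pair table,
#'   [glance()] a one-row summary.
#' @examples
#' md <- lfp_metadata("exp", "R01", fs = 100, n_channels = 2)
#' rec <- lfp_recording(cbind(a = sin(1:200), b = -sin(1:200)), md)
#' correlation_matrix(rec)$matrix
#' @export
correlation_matrix <- function(recording, t_start = 0, t_end = NULL) {
  stopifnot(inherits(recording, "lfp_recording"))
  k <- length(recording$channel_labels)
  if (k < 2) stop("shape error: need at least 2 channels", call. = FALSE)
  fs <- recording$metadata$fs
  dur <- lfp_duration(recording)
  if (is.null(t_end)) t_end <- dur
  if (t_start < 0 || t_end > dur + 1e-9 || t_end <= t_start) {
    stop("range error: span must lie within the recording", call. = FALSE)
  }
  i0 <- floor(t_start * fs + 1e-9) + 1L
  i1 <- ceiling(t_end * fs - 1e-9)
  m <- matrix(NA_real_, k, k,
              dimnames = list(recording$channel_labels, recording$channel_labels))
  diag(m) <- 1
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      r <- tryCatch(
        pearson_components(recording$data[[i]][i0:i1],
                           recording$data[[j]][i0:i1])$r,
        error = function(e) NA_real_
      )
      m[i, j] <- r
      m[j, i] <- r
    }
  }
  structure(
    list(matrix = m, t_start = t_start, t_end = t_end,
         metadata = recording$metadata),
    class = "lfp_correlation"
  )
}

#' @export
print.lfp_correlation <- function(x, ...) {
  cat(sprintf("<lfp_correlation> span [%g, %g) s\n", x$t_start, x$t_end))
  print(round(x$matrix, 4))
  invisible(x)
}

#' @method tidy lfp_correlation
#' @export
tidy.lfp_correlation <- function(x, ...) {
  m <- x$matrix
  labs <- rownames(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(channel_a = labs[idx[, 1]], channel_b = labs[idx[, 2]],
                 r = m[idx])
}

#' @method glance lfp_correlation
#' @export
glance.lfp_correlation <- function(x, ...) {
  off <- x$matrix[upper.tri(x$matrix)]
  ok <- off[!is.na(off)]
  tibble::tibble(n_channels = nrow(x$matrix),
                 r_mean = if (length(ok)) mean(ok) else NA_real_,
                 r_min = if (length(ok)) min(ok) else NA_real_,
                 r_max = if (length(ok)) max(ok) else NA_real_,
                 n_undefined = sum(is.na(off)),
                 t_start = x$t_start, t_end = x$t_end)
}
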