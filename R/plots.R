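#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_step
#'   geom_col geom_tile geom_segment geom_vline geom_hline labs theme_minimal
#'   scale_fill_gradient2 geom_text coord_fixed
#' @importFrom rlang .data
NULL

#' Plot a recording's channels
#'
#' Voltage traces over time, one facet per channel.
#'
#' @param object An [lfp_recording()].
#' @param t_start,t_end Optional span to plot, in seconds.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lfp_recording
#' @export
autoplot.lfp_recording <- function(object, t_start = 0, t_end = NULL, ...) {
  df <- as_tibble(object)
  if (is.null(t_end)) t_end <- lfp_duration(object)
  df <- df[df$time_s >= t_start & df$time_s < t_end, ]
  long <- tidyr::pivot_longer(df, -"time_s",
                              names_to = "channel", values_to = "mV")
  ggplot(long, aes(x = .data$time_s, y = .data$mV)) +
    geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    labs(x = "time (s)", y = "voltage (mV)") +
    theme_minimal()
}

#' Plot detected spikes over the analyzed channel
#'
#' The channel trace with the per-window effective thresholds (moving
#' threshold floored by the fixed threshold) as a step line and the accepted
#' spikes marked at their peaks.
#'
#' @param object A `spike_detection`.
#' @param recording Optionally, the [lfp_recording()] the detection was run
#'   on; when supplied the raw trace is drawn underneath.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spike_detection
#' @export
autoplot.spike_detection <- function(object, recording = NULL, ...) {
  thr <- object$thresholds
  thr$effective <- pmax(thr$threshold_mV, object$params$fixed_thr)
  p <- ggplot()
  if (!is.null(recording)) {
    df <- as_tibble(recording)[, c("time_s", object$channel)]
    names(df)[2] <- "mV"
    df <- df[df$time_s >= object$params$t_start &
               df$time_s < object$params$t_end, ]
    p <- p + geom_line(data = df, aes(x = .data$time_s, y = .data$mV),
                       linewidth = 0.3, colour = "grey40")
  }
  p +
    geom_step(data = thr, aes(x = .data$t_start, y = .data$effective),
              colour = "steelblue") +
    geom_point(data = object$events,
               aes(x = .data$time_s, y = .data$amplitude_mV),
               colour = "firebrick", size = 1.5) +
    labs(x = "time (s)", y = "amplitude (mV)",
         title = sprintf("%d spike(s), channel '%s'",
                         nrow(object$events), object$channel)) +
    theme_minimal()
}

#' Plot the representative average spike with its slope segments
#'
#' @param object A `spike_morphology`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spike_morphology
#' @export
autoplot.spike_morphology <- function(object, ...) {
  m <- object$metrics
  ggplot(object$avg_waveform, aes(x = .data$offset_s, y = .data$mV)) +
    geom_line() +
    geom_vline(xintercept = c(m$onset_offset, 0, m$end_offset),
               linetype = "dashed", colour = "grey50") +
    labs(x = "offset from peak (s)", y = "voltage (mV)",
         title = sprintf("average of %d spikes: rising %.1f, descent %.1f, overall %.1f mV/s",
                         object$n_epochs, m$rising_slope, m$descent_slope,
                         m$overall_slope)) +
    theme_minimal()
}

#' Raster plot of the reference/comparison trains with matched pairs
#'
#' @param object A `spike_coincidence`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spike_coincidence
#' @export
autoplot.spike_coincidence <- function(object, ...) {
  ref <- tibble::tibble(time_s = object$ref_times, y = 1)
  comp <- tibble::tibble(time_s = object$comp_times, y = 0)
  p <- ggplot() +
    geom_point(data = ref, aes(x = .data$time_s, y = .data$y), shape = 3) +
    geom_point(data = comp, aes(x = .data$time_s, y = .data$y), shape = 3)
  if (nrow(object$pairs)) {
    p <- p + geom_segment(data = object$pairs,
                          aes(x = .data$ref_time, xend = .data$comp_time,
                              y = 1, yend = 0),
                          colour = "firebrick", alpha = 0.6)
  }
  p +
    ggplot2::scale_y_continuous(breaks = c(0, 1),
                                labels = c("comparison", "reference"),
                                limits = c(-0.2, 1.2)) +
    labs(x = "time (s)", y = NULL,
         title = sprintf("%.1f%% of reference spikes coincident (window %g s)",
                         object$percent, object$window)) +
    theme_minimal()
}

#' Heat map of the channel correlation matrix
#'
#' @param object An `lfp_correlation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lfp_correlation
#' @export
autoplot.lfp_correlation <- function(object, ...) {
  m <- object$matrix
  df <- tidyr::expand_grid(channel_a = rownames(m), channel_b = colnames(m))
  df$r <- as.vector(t(m))
  ggplot(df, aes(x = .data$channel_b, y = .data$channel_a, fill = .data$r)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$r)), size = 3) +
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                         limits = c(-1, 1)) +
    coord_fixed() +
    labs(x = NULL, y = NULL,
         title = sprintf("Pearson correlation, [%g, %g) s",
                         object$t_start, object$t_end)) +
    theme_minimal()
}
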