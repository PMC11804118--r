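#' Write an analysis result as a self-describing JSON document
#'
#' Every result document has two top-level sections: `experiment` (the
#' recording metadata) and `analysis` (the analysis type, its parameters and
#' its outputs), so a saved file is interpretable on its own and round-trips
#' losslessly through [read_result()].
#'
#' @param result A `spike_detection`, `spike_morphology`, `spike_coincidence`
#'   or `lfp_correlation` object.
#' @param path Destination path (see [result_path()] for deterministic
#'   naming).
#' @param metadata Optional [lfp_metadata()] overriding the metadata carried
#'   by the result.
#' @return The written path, invisibly.
#' @export
write_result <- function(result, path, metadata = NULL) {
  md <- metadata %||% result$metadata
  if (is.null(md)) {
    stop("I/O error: result carries no metadata; supply `metadata`", call. = FALSE)
  }
  doc <- list(experiment = unclass(md),
              analysis = .analysis_section(result))
  ok <- tryCatch({
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null", pretty = TRUE)
    TRUE
  }, error = function(e) {
    stop(sprintf("I/O error: cannot write '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(path)
}

.analysis_section <- function(result) UseMethod(".analysis_section")

.analysis_section.spike_detection <- function(result) {
  list(type = "detection",
       channel = result$channel,
       params = result$params,
       outputs = list(events = result$events,
                      thresholds = result$thresholds,
                      summary = result$summary))
}

.analysis_section.spike_morphology <- function(result) {
  list(type = "morphology",
       channel = result$channel,
       params = list(half_width = result$half_width),
       outputs = list(avg_waveform = result$avg_waveform,
                      n_epochs = result$n_epochs,
                      n_dropped = result$n_dropped,
                      n_flipped = result$n_flipped,
                      metrics = result$metrics))
}

.analysis_section.spike_coincidence <- function(result) {
  list(type = "coincidence",
       params = list(window = result$window,
                     t_start = result$t_start, t_end = result$t_end),
       outputs = list(pairs = result$pairs,
                      n_ref = result$n_ref, n_comp = result$n_comp,
                      n_matched = result$n_matched,
                      percent = result$percent,
                      rate_per_s = result$rate_per_s,
                      ref_times = result$ref_times,
                      comp_times = result$comp_times))
}

.analysis_section.lfp_correlation <- function(result) {
  list(type = "correlation",
       params = list(t_start = result$t_start, t_end = result$t_end),
       outputs = list(channels = rownames(result$matrix),
                      matrix = unname(result$matrix)))
}

.as_tbl <- function(x, cols) {
  # fromJSON yields an empty list for an empty table
  if (is.null(x) || (is.list(x) && !length(x)) ||
      (is.data.frame(x) && !nrow(x))) {
    out <- lapply(cols, function(type) vector(type, 0))
    names(out) <- names(cols)
    return(tibble::as_tibble(out))
  }
  out <- tibble::as_tibble(x)
  for (nm in names(cols)) {
    coerce <- switch(cols[[nm]], numeric = as.numeric, integer = as.integer,
                     character = as.character)
    out[[nm]] <- coerce(out[[nm]])
  }
  out[names(cols)]
}

#' Read back a result document written by [write_result()]
#'
#' @param path Path to a JSON result document.
#' @return The reconstructed result object, with the experiment metadata
#'   attached, equal field-by-field to what was written.
#' @export
read_result <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("I/O error: '%s' does not exist", path), call. = FALSE)
  }
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!all(c("experiment", "analysis") %in% names(doc))) {
    stop("format error: document lacks the experiment/analysis sections",
         call. = FALSE)
  }
  e <- doc$experiment
  md <- lfp_metadata(e$experiment_name, e$animal_id, e$fs,
                     researcher = e$researcher, group_id = e$group_id,
                     n_channels = e$n_channels, gain = e$gain,
                     filtered = isTRUE(e$filtered))
  a <- doc$analysis
  switch(
    a$type,
    detection = {
      ev_cols <- c(time_s = "numeric", amplitude_mV = "numeric",
                   sample_index = "integer", window_index = "integer")
      thr_cols <- c(window_index = "integer", t_start = "numeric",
                    t_end = "numeric", threshold_mV = "numeric")
      events <- .as_tbl(a$outputs$events, ev_cols)
      structure(
        list(events = events,
             thresholds = .as_tbl(a$outputs$thresholds, thr_cols),
             params = a$params,
             summary = detection_summary(events, a$params$t_start,
                                         a$params$t_end),
             channel = a$channel, metadata = md),
        class = "spike_detection")
    },
    morphology = {
      wf <- .as_tbl(a$outputs$avg_waveform,
                    c(offset_s = "numeric", mV = "numeric"))
      structure(
        list(avg_waveform = wf,
             n_epochs = as.integer(a$outputs$n_epochs),
             n_dropped = as.integer(a$outputs$n_dropped),
             n_flipped = as.integer(a$outputs$n_flipped),
             metrics = tibble::as_tibble(a$outputs$metrics),
             half_width = a$params$half_width,
             channel = a$channel, metadata = md),
        class = "spike_morphology")
    },
    coincidence = {
      structure(
        list(pairs = .as_tbl(a$outputs$pairs,
                             c(ref_time = "numeric", comp_time = "numeric",
                               dt = "numeric")),
             n_ref = as.integer(a$outputs$n_ref),
             n_comp = as.integer(a$outputs$n_comp),
             n_matched = as.integer(a$outputs$n_matched),
             percent = a$outputs$percent,
             rate_per_s = a$outputs$rate_per_s,
             window = a$params$window,
             t_start = a$params$t_start, t_end = a$params$t_end,
             ref_times = as.numeric(unlist(a$outputs$ref_times)),
             comp_times = as.numeric(unlist(a$outputs$comp_times)),
             metadata = md),
        class = "spike_coincidence")
    },
    correlation = {
      m <- a$outputs$matrix
      labs <- a$outputs$channels
      dimnames(m) <- list(labs, labs)
      structure(
        list(matrix = m, t_start = a$params$t_start, t_end = a$params$t_end,
             metadata = md),
        class = "lfp_correlation")
    },
    stop(sprintf("format error: unknown analysis type '%s'", a$type),
         call. = FALSE)
  )
}

#' Export the detected spike events as a CSV table
#'
#' @param detection A `spike_detection`.
#' @param path Destination CSV path.
#' @return The written path, invisibly. Columns: `time_s`, `amplitude_mV`,
#'   `channel`, `window_index`.
#' @export
write_events_csv <- function(detection, path) {
  stopifnot(inherits(detection, "spike_detection"))
  ev <- detection$events
  out <- tibble::tibble(time_s = ev$time_s, amplitude_mV = ev$amplitude_mV,
                        channel = detection$channel,
                        window_index = ev$window_index)
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a recording's channels as a CSV file (one column per channel)
#'
#' The inverse of [read_recording()] for the CSV format at gain 1: values are
#' written in mV with a header row of channel labels.
#'
#' @param recording An [lfp_recording()].
#' @param path Destination CSV path.
#' @return The written path, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "lfp_recording"))
  readr::write_csv(recording$data, path)
  invisible(path)
}
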