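#' Experiment metadata for an LFP recording
#'
#' Bundles the experiment bookkeeping that travels with every analysis:
#' who recorded what, from which animal, at which sampling frequency and
#' amplification gain. `animal_id` and `experiment_name` drive the
#' deterministic output naming used by [result_path()].
#'
#' @param experiment_name Non-empty experiment name.
#' @param animal_id Non-empty animal identifier (used in output file names).
#' @param fs Sampling frequency in Hz, > 0.
#' @param researcher Researcher name (free text).
#' @param group_id Experimental group identifier.
#' @param n_channels Number of recorded channels, >= 1.
#' @param gain Amplification gain of the acquisition chain, > 0
#'   (dimensionless). Raw samples are divided by it at load time to recover
#'   millivolts.
#' @param filtered Logical flag: has the recording already been bandpass
#'   filtered?
#'
#' @return An object of class `lfp_metadata` (a named list).
#' @examples
#' md <- lfp_metadata("pilo-model", "R01", fs = 1000, gain = 1000)
#' md$fs
#' @export
lfp_metadata <- function(experiment_name, animal_id, fs,
                         researcher = "", group_id = "",
                         n_channels = 1L, gain = 1, filtered = FALSE) {
  if (!is.character(experiment_name) || length(experiment_name) != 1L ||
      !nzchar(experiment_name)) {
    stop("`experiment_name` must be a non-empty string", call. = FALSE)
  }
  if (!is.character(animal_id) || length(animal_id) != 1L || !nzchar(animal_id)) {
    stop("`animal_id` must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (!is.numeric(gain) || length(gain) != 1L || !is.finite(gain) || gain <= 0) {
    stop("`gain` must be a single positive number", call. = FALSE)
  }
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 1L) {
    stop("`n_channels` must be an integer >= 1", call. = FALSE)
  }
  structure(
    list(
      experiment_name = experiment_name,
      researcher = as.character(researcher),
      animal_id = animal_id,
      group_id = as.character(group_id),
      n_channels = n_channels,
      fs = as.numeric(fs),
      gain = as.numeric(gain),
      filtered = isTRUE(filtered)
    ),
    class = "lfp_metadata"
  )
}

#' @export
print.lfp_metadata <- function(x, ...) {
  cat("<lfp_metadata>", x$experiment_name, "/ animal", x$animal_id, "\n")
  cat("  channels:", x$n_channels, " fs:", x$fs, "Hz  gain:", x$gain,
      if (x$filtered) " (filtered)" else "", "\n")
  invisible(x)
}

#' Deterministic output path for a saved analysis result
#'
#' Builds the file name `{analysis_type}_{animal_id}[_{channel}].{ext}` so
#' repeated analyses of the same animal and channel never collide with other
#' animals or analysis types, and repeated calls always name the same file.
#' Characters that are illegal in file names are replaced by underscores.
#'
#' @param metadata An [lfp_metadata()] object (its `animal_id` is used).
#' @param analysis_type Non-empty label, e.g. `"detection"`.
#' @param channel Optional channel label appended to the name; `NULL` to omit.
#' @param ext File extension without the dot.
#' @param dir Optional directory prepended with [file.path()].
#'
#' @return The path as a single string. Pure: identical inputs give
#'   identical output; the caller decides any overwrite policy.
#' @examples
#' md <- lfp_metadata("exp", "R01", fs = 1000)
#' result_path(md, "detection", channel = "ctx")
#' @export
result_path <- function(metadata, analysis_type, channel = NULL,
                        ext = "json", dir = NULL) {
  stopifnot(inherits(metadata, "lfp_metadata"))
  if (!is.character(analysis_type) || !nzchar(analysis_type)) {
    stop("`analysis_type` must be a non-empty string", call. = FALSE)
  }
  sanitize <- function(s) gsub("[^A-Za-z0-9.-]+", "_", s)
  parts <- c(sanitize(analysis_type), sanitize(metadata$animal_id))
  if (!is.null(channel) && nzchar(channel)) parts <- c(parts, sanitize(channel))
  fn <- paste0(paste(parts, collapse = "_"), ".", sanitize(ext))
  if (is.null(dir)) fn else file.path(dir, fn)
}
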