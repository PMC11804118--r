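#' An in-memory multichannel LFP recording
#'
#' Holds gain-corrected voltage traces (mV) as a wide tibble, one column per
#' channel, together with the experiment metadata. All channels must have the
#' same number of samples and every sample must be finite. Time is seconds
#' from recording start; sample `i` (1-based) sits at `(i - 1) / fs`.
#'
#' @param data A numeric matrix, data frame or tibble, samples in rows and
#'   one column per channel, in millivolts.
#' @param metadata An [lfp_metadata()] object; `n_channels` must match
#'   `ncol(data)`.
#' @param channel_labels Optional channel names; defaults to the column names
#'   of `data` or `ch1, ch2, ...`.
#'
#' @return An object of class `lfp_recording`: a list with elements
#'   `metadata`, `channel_labels` and `data` (a tibble).
#' @examples
#' md <- lfp_metadata("exp", "R01", fs = 1000, n_channels = 2)
#' rec <- lfp_recording(cbind(ctx = sin(1:100), hpc = cos(1:100)), md)
#' lfp_duration(rec)
#' @export
lfp_recording <- function(data, metadata, channel_labels = NULL) {
  stopifnot(inherits(metadata, "lfp_metadata"))
  data <- as.data.frame(data)
  if (ncol(data) != metadata$n_channels) {
    stop(sprintf("shape error: data has %d channels but metadata declares %d",
                 ncol(data), metadata$n_channels), call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- colnames(data)
    if (is.null(channel_labels) || any(!nzchar(channel_labels)) ||
        all(grepl("^V[0-9]+$", channel_labels))) {
      channel_labels <- paste0("ch", seq_len(ncol(data)))
    }
  }
  if (length(channel_labels) != ncol(data)) {
    stop("shape error: length(channel_labels) must equal the channel count",
         call. = FALSE)
  }
  names(data) <- channel_labels
  for (ch in channel_labels) {
    v <- data[[ch]]
    if (!is.numeric(v)) {
      stop(sprintf("data error: channel '%s' is not numeric", ch), call. = FALSE)
    }
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("data error: non-finite sample in channel '%s' at index %d",
                   ch, bad[1]), call. = FALSE)
    }
  }
  structure(
    list(metadata = metadata,
         channel_labels = channel_labels,
         data = tibble::as_tibble(data)),
    class = "lfp_recording"
  )
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat("<lfp_recording>", x$metadata$experiment_name,
      "/ animal", x$metadata$animal_id, "\n")
  cat(sprintf("  %d channel(s) [%s], %d samples @ %g Hz = %.3f s\n",
              length(x$channel_labels),
              paste(x$channel_labels, collapse = ", "),
              nrow(x$data), x$metadata$fs, lfp_duration(x)))
  invisible(x)
}

#' Recording duration in seconds
#' @param recording An [lfp_recording()].
#' @return `n_samples / fs`, in seconds.
#' @export
lfp_duration <- function(recording) {
  stopifnot(inherits(recording, "lfp_recording"))
  nrow(recording$data) / recording$metadata$fs
}

#' Extract one channel as a numeric vector
#' @param recording An [lfp_recording()].
#' @param channel Channel label or 1-based index.
#' @return The channel's samples in mV.
#' @export
lfp_channel <- function(recording, channel) {
  stopifnot(inherits(recording, "lfp_recording"))
  if (is.numeric(channel)) channel <- recording$channel_labels[channel]
  if (is.na(channel) || !channel %in% recording$channel_labels) {
    stop(sprintf("lookup error: unknown channel '%s' (have: %s)",
                 channel, paste(recording$channel_labels, collapse = ", ")),
         call. = FALSE)
  }
  recording$data[[channel]]
}

#' @importFrom tibble as_tibble
#' @method as_tibble lfp_recording
#' @export
as_tibble.lfp_recording <- function(x, ...) {
  fs <- x$metadata$fs
  dplyr::bind_cols(
    tibble::tibble(time_s = (seq_len(nrow(x$data)) - 1) / fs),
    x$data
  )
}

# first line of a delimited file that is not parseable as all-numeric
# indicates a header row
.csv_has_header <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("format error: empty file", call. = FALSE)
  fields <- strsplit(first, ",", fixed = TRUE)[[1]]
  any(is.na(suppressWarnings(as.numeric(fields))))
}

#' Read a multichannel LFP recording from disk
#'
#' Reads CSV (one column per channel, optional single header row
#' auto-detected by a non-numeric first line), HDF5 (a 2-D channels x samples
#' or samples x channels dataset, or one 1-D dataset per channel), or EDF.
#' For CSV and HDF5 the raw values are in recorded units and are divided by
#' `metadata$gain` to yield millivolts. For EDF the header's sampling
#' frequency and channel labels override the metadata (with a warning on
#' mismatch) and the header's digital-to-physical calibration replaces the
#' gain division.
#'
#' HDF5 support is bridged through a `python` interpreter with `h5py` on the
#' PATH (no R HDF5 interface is required).
#'
#' @param path Path to the file.
#' @param metadata An [lfp_metadata()] describing the recording.
#' @param format One of `"csv"`, `"hdf5"`, `"edf"`; default guessed from the
#'   file extension.
#' @return An [lfp_recording()] with gain-corrected data in mV.
#' @export
read_recording <- function(path, metadata,
                           format = c("auto", "csv", "hdf5", "edf")) {
  stopifnot(inherits(metadata, "lfp_metadata"))
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("format error: file '%s' does not exist", path), call. = FALSE)
  }
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", txt = "csv",
                     h5 = "hdf5", hdf5 = "hdf5",
                     edf = "edf",
                     stop("format error: cannot guess format from extension; pass `format`",
                          call. = FALSE))
  }
  switch(format,
         csv = .read_recording_csv(path, metadata),
         hdf5 = .read_recording_hdf5(path, metadata),
         edf = .read_recording_edf(path, metadata))
}

.read_recording_csv <- function(path, metadata) {
  has_header <- .csv_has_header(path)
  df <- tryCatch(
    readr::read_csv(path, col_names = has_header, show_col_types = FALSE,
                    progress = FALSE,
                    col_types = readr::cols(.default = readr::col_double())),
    error = function(e) stop(sprintf("format error: cannot parse '%s' as CSV: %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  if (ncol(df) != metadata$n_channels) {
    stop(sprintf("shape error: '%s' has %d columns but metadata declares %d channels",
                 path, ncol(df), metadata$n_channels), call. = FALSE)
  }
  labels <- if (has_header) names(df) else paste0("ch", seq_len(ncol(df)))
  lfp_recording(as.data.frame(df) / metadata$gain, metadata, labels)
}

.read_recording_hdf5 <- function(path, metadata) {
  py <- Sys.which("python")
  if (!nzchar(py)) {
    stop("format error: HDF5 reading needs a `python` with h5py on the PATH",
         call. = FALSE)
  }
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp), add = TRUE)
  code <- paste(
    "import sys, h5py, numpy as np",
    "f = h5py.File(sys.argv[1], 'r')",
    "keys = sorted(f.keys())",
    "ds = [np.asarray(f[k]) for k in keys]",
    "if len(ds) == 1 and ds[0].ndim == 2:",
    "    a = ds[0]; a = a.T if a.shape[0] < a.shape[1] else a",
    "    names = [f'ch{i+1}' for i in range(a.shape[1])]",
    "else:",
    "    a = np.column_stack(ds); names = keys",
    "np.savetxt(sys.argv[2], a, delimiter=',', header=','.join(names), comments='')",
    sep = "\n")
  status <- system2(py, c("-c", shQuote(code), shQuote(path), shQuote(tmp)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(tmp)) {
    stop(sprintf("format error: cannot read '%s' as HDF5", path), call. = FALSE)
  }
  .read_recording_csv(tmp, metadata)
}

# Minimal EDF reader: 256-byte ASCII main header, 256 bytes per signal of
# per-signal header fields, then data records of interleaved int16 samples.
# Digital values are mapped to physical units with the per-signal linear
# calibration from the header.
.read_recording_edf <- function(path, metadata) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(n) {
    raw <- readBin(con, "raw", n)
    if (length(raw) < n) stop("format error: truncated EDF header", call. = FALSE)
    trimws(rawToChar(raw))
  }
  rd(8)                       # version
  rd(80); rd(80); rd(8); rd(8) # patient, recording, date, time
  rd(8)                       # header bytes
  rd(44)                      # reserved
  n_records <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L || is.na(n_records) || n_records < 1L ||
      is.na(record_dur) || record_dur <= 0) {
    stop("format error: invalid EDF header", call. = FALSE)
  }
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fld(16)
  fld(80); fld(8)             # transducer, dimension
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)                     # prefiltering
  n_samp <- as.integer(fld(8))
  fld(32)                     # reserved
  if (length(unique(n_samp)) != 1L) {
    stop("format error: per-signal sampling rates differ; not supported",
         call. = FALSE)
  }
  fs_edf <- n_samp[1] / record_dur
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - scale * dig_min
  out <- matrix(NA_real_, nrow = n_records * n_samp[1], ncol = ns)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      v <- readBin(con, "integer", n = n_samp[s], size = 2, endian = "little")
      if (length(v) < n_samp[s]) stop("format error: truncated EDF data",
                                      call. = FALSE)
      rows <- ((r - 1) * n_samp[s] + 1):(r * n_samp[s])
      out[rows, s] <- v * scale[s] + offset[s]
    }
  }
  if (ns != metadata$n_channels) {
    stop(sprintf("shape error: EDF has %d signals but metadata declares %d channels",
                 ns, metadata$n_channels), call. = FALSE)
  }
  if (!isTRUE(all.equal(fs_edf, metadata$fs))) {
    warning(sprintf("EDF header fs (%g Hz) overrides metadata fs (%g Hz)",
                    fs_edf, metadata$fs))
    metadata$fs <- fs_edf
  }
  lfp_recording(out, metadata, labels)
}
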