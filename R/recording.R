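#' Construct an EEG recording
#'
#' An `eeg_recording` holds one trial's multichannel EEG as a channels x
#' samples matrix (microvolts) together with its sampling rate, channel
#' labels, provenance identifiers, and whatever affective annotation the
#' trial carries: a discrete emotion label (e.g. positive/neutral/negative),
#' continuous 1-9 valence/arousal self-ratings, or both.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param sampling_rate sampling rate in Hz (positive).
#' @param channel_names character vector, one name per row of `data`.
#'   Defaults to `ch1..chN`.
#' @param subject_id,trial_id provenance strings.
#' @param label optional discrete emotion label (character).
#' @param valence,arousal optional self-ratings on the 1-9 scale.
#' @return an object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(4 * 100), 4), sampling_rate = 50)
#' dim(rec$data)
#' @export
eeg_recording <- function(data, sampling_rate, channel_names = NULL,
                          subject_id = "s01", trial_id = "t01",
                          label = NULL, valence = NULL, arousal = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stopf("`data` must be a numeric channels x samples matrix")
  if (ncol(data) < 1) stopf("recording must contain at least one sample")
  if (!is_count(sampling_rate)) stopf("`sampling_rate` must be a positive integer (Hz)")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stopf("%d channel names for %d data rows", length(channel_names), nrow(data))
  if (!is.null(valence) && (valence < 1 || valence > 9))
    stopf("valence rating %.3g outside [1, 9]", valence)
  if (!is.null(arousal) && (arousal < 1 || arousal > 9))
    stopf("arousal rating %.3g outside [1, 9]", arousal)
  structure(list(
    data = unname(data),
    sampling_rate = as.integer(sampling_rate),
    channel_names = as.character(channel_names),
    subject_id = as.character(subject_id),
    trial_id = as.character(trial_id),
    label = if (is.null(label)) NULL else as.character(label),
    valence = if (is.null(valence)) NULL else as.numeric(valence),
    arousal = if (is.null(arousal)) NULL else as.numeric(arousal)
  ), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s/%s: %d channels x %d samples @ %d Hz (%.1f s)\n",
              x$subject_id, x$trial_id, nrow(x$data), ncol(x$data),
              x$sampling_rate, ncol(x$data) / x$sampling_rate))
  if (!is.null(x$label)) cat("  label:", x$label, "\n")
  if (!is.null(x$valence) || !is.null(x$arousal))
    cat(sprintf("  ratings: valence %s, arousal %s\n",
                x$valence %||% "-", x$arousal %||% "-"))
  invisible(x)
}

# ---- binary matrix-container + JSON sidecar ---------------------------------

sidecar_path <- function(path) sub("\\.bin$", ".json", path)

#' Write a recording to the binary matrix-container format
#'
#' The container is a raw little-endian 32-bit float dump of the channels x
#' samples matrix in row-major order (`<path>.bin`), plus a JSON sidecar
#' (`<path>.json`) holding the sampling rate, channel names, provenance and
#' labels/ratings. Values are stored at float32 precision.
#'
#' @param rec an [eeg_recording].
#' @param path output path for the data file; `.bin` is appended when absent,
#'   and the sidecar replaces that extension with `.json`.
#' @return the data-file path, invisibly.
#' @seealso [read_recording()], [load_recording()]
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!grepl("\\.bin$", path)) path <- paste0(path, ".bin")
  con <- file(path, "wb")
  on.exit(close(con))
  # row-major: sample index varies fastest
  writeBin(as.numeric(t(rec$data)), con, size = 4, endian = "little")
  meta <- list(sampling_rate = rec$sampling_rate,
               channel_names = rec$channel_names,
               subject_id = rec$subject_id, trial_id = rec$trial_id)
  if (!is.null(rec$label)) meta$label <- rec$label
  if (!is.null(rec$valence)) meta$valence <- rec$valence
  if (!is.null(rec$arousal)) meta$arousal <- rec$arousal
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording from the binary matrix-container format
#'
#' @param path path to the `.bin` data file written by [write_recording()];
#'   its `.json` sidecar must sit alongside.
#' @return an [eeg_recording].
#' @export
read_recording <- function(path) {
  if (!grepl("\\.bin$", path)) path <- paste0(path, ".bin")
  if (!file.exists(path)) stopf("data file not found: %s", path)
  side <- sidecar_path(path)
  if (!file.exists(side)) stopf("JSON sidecar not found: %s", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (f in c("sampling_rate", "channel_names")) if (is.null(meta[[f]]))
    stopf("sidecar %s lacks required field '%s'", side, f)
  n_bytes <- file.size(path)
  if (n_bytes %% 4 != 0) stopf("corrupt data file (size not a multiple of 4): %s", path)
  vals <- readBin(path, "numeric", n = n_bytes / 4, size = 4, endian = "little")
  n_ch <- length(meta$channel_names)
  if (length(vals) %% n_ch != 0)
    stopf("%d float32 values do not fill %d channels evenly", length(vals), n_ch)
  data <- matrix(vals, nrow = n_ch, byrow = TRUE)
  eeg_recording(data, meta$sampling_rate, meta$channel_names,
                subject_id = meta$subject_id %||% "s01",
                trial_id = meta$trial_id %||% "t01",
                label = meta$label, valence = meta$valence, arousal = meta$arousal)
}

#' Load a recording from disk
#'
#' Dispatches on format: the binary matrix-container (`.bin` + `.json`
#' sidecar) or EDF. `"auto"` decides from the file extension.
#'
#' @param path input file path.
#' @param format one of `"auto"`, `"container"`, `"edf"`.
#' @return an [eeg_recording].
#' @export
load_recording <- function(path, format = c("auto", "container", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "container"
  switch(format, container = read_recording(path), edf = read_edf(path))
}
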