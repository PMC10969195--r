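# Minimal EDF (European Data Format) reader/writer.
#
# EDF stores a fixed-layout ASCII header (256 bytes + 256 per signal) followed
# by data records of little-endian 16-bit integers, one contiguous block per
# signal per record, mapped linearly between the digital and physical ranges.
# This implementation covers continuous equal-rate signals, which is all an
# emotion-classification pipeline needs; annotations (EDF+) are out of scope.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as an EDF file
#'
#' All channels are written into a single data record spanning the whole
#' recording, quantized to the EDF 16-bit digital range over each channel's
#' observed physical range (in microvolts). Quantization error is bounded by
#' (max - min) / 65535 per channel. Labels and ratings have no EDF slot and
#' are not stored.
#'
#' @param rec an [eeg_recording].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_ch <- nrow(rec$data); n_samp <- ncol(rec$data)
  dig_min <- -32768; dig_max <- 32767
  phys_min <- apply(rec$data, 1, min); phys_max <- apply(rec$data, 1, max)
  flat <- phys_max - phys_min < 1e-12        # constant channels: avoid 0 range
  phys_max[flat] <- phys_min[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),                                        # version
    edf_pad(rec$subject_id, 80),                            # patient id
    edf_pad(rec$trial_id, 80),                              # recording id
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),         # start date/time
    edf_pad(256 * (1 + n_ch), 8),                           # header bytes
    edf_pad("", 44),
    edf_pad(1, 8),                                          # n data records
    edf_pad(format(n_samp / rec$sampling_rate, digits = 7), 8), # record seconds
    edf_pad(n_ch, 4))
  field <- function(vals, width) paste(vapply(vals, edf_pad, "", width = width),
                                       collapse = "")
  hdr <- paste0(hdr,
    field(rec$channel_names, 16),
    field(rep("", n_ch), 80),                               # transducer
    field(rep("uV", n_ch), 8),                              # physical dimension
    field(format(phys_min, digits = 7), 8),
    field(format(phys_max, digits = 7), 8),
    field(rep(dig_min, n_ch), 8),
    field(rep(dig_max, n_ch), 8),
    field(rep("", n_ch), 80),                               # prefiltering
    field(rep(n_samp, n_ch), 8),                            # samples per record
    field(rep("", n_ch), 32))
  writeChar(hdr, con, eos = NULL)
  for (c_i in seq_len(n_ch)) {
    scale <- (dig_max - dig_min) / (phys_max[c_i] - phys_min[c_i])
    dig <- round((rec$data[c_i, ] - phys_min[c_i]) * scale + dig_min)
    writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file as a recording
#'
#' @param path path to an EDF file with equal sampling rates across signals.
#' @return an [eeg_recording]; subject and trial identifiers are taken from
#'   the EDF patient and recording fields.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stopf("EDF file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  subject_id <- rd(80); trial_id <- rd(80)
  rd(8); rd(8)                                   # start date/time, unused
  header_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_sec <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  if (is.na(n_ch) || n_ch < 1) stopf("corrupt EDF header in %s", path)
  if (header_bytes != 256 * (1 + n_ch))
    stopf("EDF header length field (%d) inconsistent with %d signals",
          header_bytes, n_ch)
  rdv <- function(width) vapply(seq_len(n_ch), function(i) rd(width), "")
  ch_names <- rdv(16); rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8)); phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8)); dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  if (length(unique(spr)) != 1)
    stopf("mixed per-signal sampling rates are not supported")
  n_samp <- spr[1]
  data <- matrix(0, n_ch, n_samp * n_rec)
  for (r in seq_len(n_rec)) for (c_i in seq_len(n_ch)) {
    dig <- readBin(con, "integer", n = n_samp, size = 2, endian = "little")
    if (length(dig) < n_samp) stopf("truncated EDF data in %s", path)
    gain <- (phys_max[c_i] - phys_min[c_i]) / (dig_max[c_i] - dig_min[c_i])
    data[c_i, (r - 1) * n_samp + seq_len(n_samp)] <-
      (dig - dig_min[c_i]) * gain + phys_min[c_i]
  }
  rate <- n_samp / (rec_sec / 1)
  if (abs(rate - round(rate)) > 1e-6)
    stopf("non-integer sampling rate (%g Hz) in %s", rate, path)
  eeg_recording(data, round(rate), ch_names,
                subject_id = if (nzchar(subject_id)) subject_id else "s01",
                trial_id = if (nzchar(trial_id)) trial_id else "t01")
}
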