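# Minimal European Data Format (EDF) writer/reader for continuous
# recordings: 16-bit samples, one set of physical/digital scaling values
# per channel, fixed-length data records. Covers the subset of the
# format this package produces and consumes (no annotations).

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 6)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4)
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16-bit integers over each channel's observed
#' physical range, so round-tripping preserves the signal up to
#' quantization (relative error on the order of 1/65536 of the channel
#' range).
#'
#' @param rec An [new_recording()].
#' @param path Output file.
#' @param record_s Data-record duration in seconds.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$signal)
  spr <- round(rec$sr * record_s)
  n_rec <- ceiling(ncol(rec$signal) / spr)
  total <- n_rec * spr
  sig <- cbind(rec$signal,
               matrix(0, ns, total - ncol(rec$signal)))
  pmax_ <- apply(abs(sig), 1, max)
  pmax_ <- ifelse(pmax_ == 0, 1, pmax_ * 1.0001)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("synthetic subject", 80),
    edf_pad("oddballAEP simulated recording", 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_num(record_s, 8),
    edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  }
  labs <- rec$channel_names
  field(labs, 16)
  field(rep("EEG electrode", ns), 80)
  field(rep("uV", ns), 8)
  field(vapply(-pmax_, edf_num, ""), 8)
  field(vapply(pmax_, edf_num, ""), 8)
  field(rep("-32768", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("", ns), 80)
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)

  # re-read the ascii physical bounds so scaling matches what a reader
  # will parse
  pmin_r <- as.numeric(vapply(-pmax_, edf_num, ""))
  pmax_r <- as.numeric(vapply(pmax_, edf_num, ""))
  scale <- (pmax_r - pmin_r) / (32767 - (-32768))
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((sig[ch, cols] - pmin_r[ch]) / scale[ch]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @param sr_override Use this sampling rate instead of the one implied
#'   by the record duration (useful when the duration field lost
#'   precision).
#' @return `read_edf` returns an [new_recording()] (without events).
#' @export
read_edf <- function(path, sr_override = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  record_s <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labs <- rdv(16)
  rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8))
  pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  sig <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      cols <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      sig[ch, cols] <- pmin_[ch] + (dig - dmin[ch]) * scale[ch]
    }
  }
  rownames(sig) <- labs
  sr <- sr_override %||% (spr[1] / record_s)
  new_recording(sig, sr, events = NULL, reference = "unknown")
}
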