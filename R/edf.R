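# EDF (European Data Format) input/output.
#
# EDF stores a fixed-layout ASCII header followed by 16-bit little-endian
# data records; each channel declares a physical (microvolt) and digital
# range, and samples are linearly rescaled between the two. One data
# record per second is written here, so the sampling rate must be a whole
# number of samples per second.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, width = width, format = "g", digits = 7)
  if (nchar(s) > width) s <- substr(format(x, scientific = FALSE), 1, width)
  edf_pad(trimws(s), width)
}

#' Write a recording to an EDF file
#'
#' Samples are scaled to 16-bit integers against a per-channel physical
#' range taken from the data, so the roundtrip quantization error is at
#' most `physical_range / 2^16` per sample. The channel class is stored in
#' the transducer field and recovered by [read_edf()].
#'
#' @param recording a [new_recording()] object; `fs` must be an integer and
#'   all samples finite.
#' @param path output file path.
#'
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  data <- recording$data
  fs <- recording$fs
  if (fs != round(fs)) abort("EDF writer requires an integer sampling rate")
  if (any(!is.finite(data))) abort("samples must be finite to write EDF")
  nchan <- ncol(data)
  if (nchan < 1) abort("recording has no channels")
  n_rec <- floor(nrow(data) / fs)
  if (n_rec < 1) abort("recording shorter than one 1-s data record")
  if (n_rec * fs < nrow(data)) {
    warn(sprintf("truncating %d trailing samples (partial data record)",
                 nrow(data) - n_rec * fs))
    data <- data[seq_len(n_rec * fs), , drop = FALSE]
  }

  pmin <- apply(data, 2, min)
  pmax <- apply(data, 2, max)
  flat <- pmax - pmin <= 0
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768
  dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)

  header_bytes <- 256 + 256 * nchan
  wr(edf_pad("0", 8))
  wr(edf_pad("X X X X", 80))
  wr(edf_pad("Startdate X X X X", 80))
  wr(edf_pad("01.01.00", 8))
  wr(edf_pad("00.00.00", 8))
  wr(edf_num(header_bytes, 8))
  wr(edf_pad("", 44))
  wr(edf_num(n_rec, 8))
  wr(edf_num(1, 8))
  wr(edf_num(nchan, 4))

  wr(paste0(vapply(recording$labels, edf_pad, "", width = 16), collapse = ""))
  wr(paste0(vapply(paste0("class: ", recording$classes), edf_pad, "",
                   width = 80), collapse = ""))
  wr(paste0(rep(edf_pad("uV", 8), nchan), collapse = ""))
  wr(paste0(vapply(pmin, edf_num, "", width = 8), collapse = ""))
  wr(paste0(vapply(pmax, edf_num, "", width = 8), collapse = ""))
  wr(paste0(rep(edf_num(dmin, 8), nchan), collapse = ""))
  wr(paste0(rep(edf_num(dmax, 8), nchan), collapse = ""))
  wr(paste0(rep(edf_pad("", 80), nchan), collapse = ""))
  wr(paste0(rep(edf_num(fs, 8), nchan), collapse = ""))
  wr(paste0(rep(edf_pad("", 32), nchan), collapse = ""))

  # digital conversion per channel
  dig <- matrix(0L, nrow = nrow(data), ncol = nchan)
  for (j in seq_len(nchan)) {
    scaled <- (data[, j] - pmin[j]) / (pmax[j] - pmin[j]) * (dmax - dmin) + dmin
    dig[, j] <- as.integer(round(pmin(pmax(scaled, dmin), dmax)))
  }
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (j in seq_len(nchan)) {
      writeBin(dig[idx, j], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Digital samples are converted to physical units (microvolts) using the
#' header scaling. All channels must share one sampling rate; mixed-rate
#' files are rejected rather than resampled. A file shorter than its header
#' declares is reported as a parse error, not silently truncated.
#'
#' @param path path to an EDF file.
#' @return A [new_recording()] object.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    raw <- readBin(con, "raw", n)
    if (length(raw) < n) abort("malformed EDF header: file too short")
    rawToChar(raw)
  }
  rd(8)                        # version
  rd(80); rd(80); rd(8); rd(8) # ids, date, time
  header_bytes <- as.numeric(rd(8))
  rd(44)
  n_rec <- as.numeric(rd(8))
  rec_dur <- as.numeric(rd(8))
  nchan <- as.numeric(rd(4))
  if (is.na(nchan) || nchan < 1 || is.na(rec_dur) || rec_dur <= 0) {
    abort("malformed EDF header")
  }
  rdv <- function(width) {
    vapply(seq_len(nchan), function(i) trimws(rd(width)), "")
  }
  labels <- rdv(16)
  transducer <- rdv(80)
  rdv(8)                              # physical dimension
  pmin <- as.numeric(rdv(8))
  pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rdv(80)                             # prefiltering
  spr <- as.numeric(rdv(8))           # samples per record
  rdv(32)
  if (any(is.na(c(pmin, pmax, dmin, dmax, spr)))) {
    abort("malformed EDF header: bad numeric field")
  }
  if (length(unique(spr)) != 1) {
    abort("mixed per-channel sampling rates are not supported")
  }
  if (!is.na(header_bytes) && header_bytes != 256 + 256 * nchan) {
    abort("malformed EDF header: inconsistent header size")
  }
  fs <- spr[1] / rec_dur

  rec_size <- sum(spr) * 2
  payload <- readBin(con, "raw", n = rec_size * max(n_rec, 0) + rec_size)
  if (n_rec < 0) {
    if (length(payload) %% rec_size != 0) {
      abort("truncated EDF file: partial data record")
    }
    n_rec <- length(payload) / rec_size
  } else if (length(payload) < rec_size * n_rec) {
    abort(sprintf(
      "truncated EDF file: header declares %d records, found %d complete",
      n_rec, floor(length(payload) / rec_size)))
  }
  payload <- payload[seq_len(rec_size * n_rec)]
  ints <- readBin(payload, "integer", n = length(payload) / 2, size = 2,
                  signed = TRUE, endian = "little")
  data <- matrix(NA_real_, nrow = n_rec * spr[1], ncol = nchan)
  per_rec <- sum(spr)
  for (r in seq_len(n_rec)) {
    base <- (r - 1) * per_rec
    for (j in seq_len(nchan)) {
      seg <- ints[(base + (j - 1) * spr[1] + 1):(base + j * spr[1])]
      data[((r - 1) * spr[1] + 1):(r * spr[1]), j] <- seg
    }
  }
  for (j in seq_len(nchan)) {
    data[, j] <- (data[, j] - dmin[j]) * (pmax[j] - pmin[j]) /
      (dmax[j] - dmin[j]) + pmin[j]
  }
  classes <- sub("^class:\\s*", "", transducer)
  classes[!classes %in% c("EEG", "EOG", "EMG")] <- "EEG"
  new_recording(data, fs, labels, classes)
}
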