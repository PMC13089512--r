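# Minimal European Data Format (EDF) I/O: continuous 16-bit records, one
# 1-second data record per block, identical sampling rate across signals.
# Written in-package because no installed R package reads or writes EDF;
# covers exactly what the pipeline needs (multichannel EEG exchange), not the
# full EDF+ annotation standard.

pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Continuous multichannel recording container
#'
#' @param data Numeric matrix, samples x channels.
#' @param fs Sampling rate (Hz).
#' @param channels Character vector of channel names (defaults to colnames).
#' @param start_s Time of the first sample in seconds (default 0).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels = colnames(data), start_s = 0) {
  data <- as.matrix(data)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(data)))
  abort_if(length(channels) != ncol(data), "one name per channel required")
  abort_if(!is.numeric(fs) || fs <= 0, "fs must be a positive sampling rate")
  colnames(data) <- channels
  structure(list(data = data, fs = fs, channels = channels, start_s = start_s),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs))
  invisible(x)
}

#' Write a recording to an EDF file
#'
#' Signals are quantized to 16 bits over their per-channel physical range and
#' stored in 1-second data records; the recording is truncated to a whole
#' number of seconds. `fs` must be an integer.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  abort_if(!inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  fs <- rec$fs
  abort_if(fs != round(fs), "write_edf requires an integer sampling rate")
  ns <- ncol(rec$data)
  n_rec <- floor(nrow(rec$data) / fs)
  abort_if(n_rec < 1, "recording shorter than one data record (1 s)")
  dat <- rec$data[seq_len(n_rec * fs), , drop = FALSE]

  pmin_ <- apply(dat, 2, min)
  pmax_ <- apply(dat, 2, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  scale <- (pmax_ - pmin_) / (dmax - dmin)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate X X X X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256L * (1L + ns), 8), pad("", 44),
    pad(n_rec, 8), pad("1", 8), pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width) writeChar(paste0(vapply(vals, pad, "", width = width),
                                                collapse = ""), con, eos = NULL)
  fld(rec$channels, 16)
  fld(rep("", ns), 80)
  fld(rep("uV", ns), 8)
  fld(sprintf("%.8g", pmin_), 8)
  fld(sprintf("%.8g", pmax_), 8)
  fld(rep(dmin, ns), 8)
  fld(rep(dmax, ns), 8)
  fld(rep("", ns), 80)
  fld(rep(fs, ns), 8)
  fld(rep("", ns), 32)

  dig <- round(sweep(sweep(dat, 2, pmin_), 2, scale, "/") + dmin)
  dig <- pmin(pmax(dig, dmin), dmax)
  # record-major, signal-major within record
  idx <- matrix(seq_len(n_rec * fs), nrow = fs)
  for (r in seq_len(n_rec)) {
    writeBin(as.integer(dig[idx[, r], ]), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any continuous 16-bit EDF
#' with a common sampling rate across signals)
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fldv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fldv(16)
  fldv(80); fldv(8)
  pmin_ <- as.numeric(fldv(8)); pmax_ <- as.numeric(fldv(8))
  dmin <- as.numeric(fldv(8)); dmax <- as.numeric(fldv(8))
  fldv(80)
  nsamp <- as.integer(fldv(8))
  fldv(32)
  abort_if(length(unique(nsamp)) != 1L,
           "read_edf supports a common sampling rate across signals only")
  fs <- nsamp[1] / rec_dur
  raw <- readBin(con, "integer", n = n_rec * sum(nsamp), size = 2L,
                 endian = "little", signed = TRUE)
  arr <- array(raw, dim = c(nsamp[1], ns, n_rec))
  dat <- matrix(aperm(arr, c(1, 3, 2)), nrow = nsamp[1] * n_rec, ncol = ns)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  dat <- sweep(sweep(dat, 2, dmin, "-"), 2, scale, "*")
  dat <- sweep(dat, 2, pmin_, "+")
  eeg_recording(dat, fs, labels)
}
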