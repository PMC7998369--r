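#' Write a recording as delimited text
#'
#' One row per sample, one tab-separated column per channel, preceded by
#' comment header lines carrying the sampling rate and channel labels.
#'
#' @param rec A `qeeg_recording`.
#' @param path Output path.
#' @export
write_recording_txt <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz: %g", rec$rate), con)
  writeLines(paste0("# channels: ", paste(rownames(rec$signal),
                                          collapse = "\t")), con)
  utils::write.table(t(rec$signal), con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
}

#' Read a delimited-text recording
#'
#' @param path Path written by [write_recording_txt()] (or any text file
#'   with the same two-line header).
#' @param montage Montage attached to the result.
#' @return A `qeeg_recording` (empty metadata).
#' @export
read_recording_txt <- function(path, montage = qeeg_montage()) {
  hdr <- readLines(path, n = 2)
  rate <- as.numeric(sub("^# rate_hz:\\s*", "", hdr[1]))
  labels <- strsplit(sub("^# channels:\\s*", "", hdr[2]), "\t")[[1]]
  m <- as.matrix(utils::read.table(path, sep = "\t", skip = 2))
  sig <- t(m)
  rownames(sig) <- labels
  rec <- list(signal = sig, rate = rate, montage = montage, meta = list())
  class(rec) <- "qeeg_recording"
  rec
}

#' Read an OpenBCI GUI decimal text export
#'
#' Comma-separated samples with metadata lines prefixed `%` and the sample
#' index in the first column; the remaining columns are taken to be the
#' recorded channels in montage order (or as named by `labels`).
#'
#' @param path Path to the exported text file.
#' @param labels Channel labels for the data columns.
#' @param rate Sampling rate in Hz (default 256).
#' @param montage Montage attached to the result.
#' @return A `qeeg_recording`.
#' @export
read_openbci_txt <- function(path, labels, rate = 256,
                             montage = qeeg_montage()) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "%") & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(lines, ","), as.numeric))
  if (ncol(m) < length(labels) + 1)
    stop("fewer data columns than channel labels")
  sig <- t(m[, 1 + seq_along(labels), drop = FALSE])
  rownames(sig) <- labels
  rec <- list(signal = sig, rate = rate, montage = montage, meta = list())
  class(rec) <- "qeeg_recording"
  rec
}

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to EDF
#'
#' Minimal continuous 16-bit EDF writer: 1-second data records, per-channel
#' physical scaling from the data range.  Partial trailing seconds are
#' truncated.
#'
#' @param rec A `qeeg_recording` with an integer sampling rate.
#' @param path Output path.
#' @export
write_edf <- function(rec, path) {
  sig <- rec$signal
  rate <- as.integer(rec$rate)
  nrec <- floor(ncol(sig) / rate)
  if (nrec < 1) stop("recording shorter than one data record")
  sig <- sig[, seq_len(nrec * rate), drop = FALSE]
  ns <- nrow(sig)
  # round outward to the 2-decimal header precision so no sample falls
  # outside the written physical range
  pmin_ <- floor(apply(sig, 1, min) * 100) / 100
  pmax_ <- ceiling(apply(sig, 1, max) * 100) / 100
  flat <- pmax_ - pmin_ < 1e-6
  pmax_[flat] <- pmin_[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_ascii("0", 8),
    pad_ascii(sprintf("subject %s", rec$meta$subject %||% "X"), 80),
    pad_ascii(sprintf("%s %s", rec$meta$environment %||% "",
                      rec$meta$task %||% ""), 80),
    pad_ascii("01.01.20", 8), pad_ascii("00.00.00", 8),
    pad_ascii(256 + 256 * ns, 8), pad_ascii("", 44),
    pad_ascii(nrec, 8), pad_ascii("1", 8), pad_ascii(ns, 4),
    paste(pad_ascii(rownames(sig), 16), collapse = ""),
    paste(rep(pad_ascii("", 80), ns), collapse = ""),
    paste(rep(pad_ascii("uV", 8), ns), collapse = ""),
    paste(pad_ascii(formatC(pmin_, format = "f", digits = 2), 8), collapse = ""),
    paste(pad_ascii(formatC(pmax_, format = "f", digits = 2), 8), collapse = ""),
    paste(rep(pad_ascii("-32768", 8), ns), collapse = ""),
    paste(rep(pad_ascii("32767", 8), ns), collapse = ""),
    paste(rep(pad_ascii("", 80), ns), collapse = ""),
    paste(rep(pad_ascii(rate, 8), ns), collapse = ""),
    paste(rep(pad_ascii("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  # re-read the ascii physical ranges so the scaling matches what a reader
  # will see after the 8-character truncation
  pmin_h <- as.numeric(pad_ascii(formatC(pmin_, format = "f", digits = 2), 8))
  pmax_h <- as.numeric(pad_ascii(formatC(pmax_, format = "f", digits = 2), 8))
  scale <- (pmax_h - pmin_h) / 65535
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * rate + 1):(r * rate)
    for (ch in seq_len(ns)) {
      dig <- round((sig[ch, idx] - pmin_h[ch]) / scale[ch]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Minimal reader for continuous 16-bit EDF files with a common sampling
#' rate across signals.
#'
#' @param path Path to an EDF file.
#' @param montage Montage attached to the result.
#' @return A `qeeg_recording`.
#' @export
read_edf <- function(path, montage = qeeg_montage()) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) trimws(readChar(con, nchars, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fld(16); fld(80); fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin_ <- as.numeric(fld(8)); dmax_ <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-signal sampling rates are not supported")
  sig <- matrix(0, ns, nrec * spr[1], dimnames = list(labels, NULL))
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[1], size = 2, endian = "little")
      sig[ch, idx] <- (dig - dmin_[ch]) *
        (pmax_[ch] - pmin_[ch]) / (dmax_[ch] - dmin_[ch]) + pmin_[ch]
    }
  }
  rec <- list(signal = sig, rate = spr[1] / dur, montage = montage,
              meta = list())
  class(rec) <- "qeeg_recording"
  rec
}

#' Write a table as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read a TSV table
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
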