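# Minimal EDF (European Data Format) writer/reader for continuous signals.
# Written in-package because no pre-installed R package provides EDF I/O.
# One data record per second, 16-bit little-endian samples, per-channel
# physical scaling; quantization error is bounded by the physical range
# divided by 2^16. Stimulus events live in a sidecar TSV (see
# [writeEventTable()]) rather than EDF+ annotations, so sample indices stay
# lossless integers.

.edfPad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a continuous multi-channel signal as EDF
#'
#' @param x channels x samples numeric matrix with channel rownames (uV), or
#'   a [SyntheticSession-class].
#' @param path output file path.
#' @param samplingRate samples per second (taken from the session when `x`
#'   is one); must be a whole number since records span one second.
#' @param startdate,starttime header fields, `"dd.mm.yy"` / `"hh.mm.ss"`.
#' @return invisibly, `path`.
#' @export
writeEdf <- function(x, path, samplingRate = NULL,
                     startdate = "01.01.26", starttime = "00.00.00") {
  if (is(x, "SyntheticSession")) {
    if (is.null(samplingRate)) samplingRate <- x@samplingRate
    x <- x@signal
  }
  stopifnot(is.matrix(x), !is.null(rownames(x)),
            samplingRate == round(samplingRate))
  nCh <- nrow(x)
  fs <- as.integer(samplingRate)
  nRec <- as.integer(ceiling(ncol(x) / fs))
  padded <- matrix(0, nCh, nRec * fs)
  padded[, seq_len(ncol(x))] <- x

  physMax <- apply(abs(padded), 1, max)
  physMax <- ifelse(physMax > 0, physMax * 1.0001, 1)
  digMax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfPad("0", 8),                        # version
    .edfPad("X X X X", 80),                 # patient id
    .edfPad("Startdate X X X X", 80),       # recording id
    .edfPad(startdate, 8), .edfPad(starttime, 8),
    .edfPad(256 * (1 + nCh), 8),            # header bytes
    .edfPad("", 44),                        # reserved
    .edfPad(nRec, 8), .edfPad("1", 8),      # n records, record duration s
    .edfPad(nCh, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width) {
    writeChar(paste(vapply(vals, .edfPad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  fld(rownames(x), 16)                      # label
  fld(rep("AgAgCl electrode", nCh), 80)     # transducer
  fld(rep("uV", nCh), 8)                    # physical dimension
  fld(sprintf("%.6g", -physMax), 8)
  fld(sprintf("%.6g", physMax), 8)
  fld(rep(-digMax, nCh), 8)
  fld(rep(digMax, nCh), 8)
  fld(rep("", nCh), 80)                     # prefiltering
  fld(rep(fs, nCh), 8)                      # samples per record
  fld(rep("", nCh), 32)                     # reserved

  scale <- digMax / physMax
  for (r in seq_len(nRec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    block <- round(padded[, cols, drop = FALSE] * scale)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [writeEdf()]
#'
#' Supports the plain 16-bit EDF layout this package writes (uniform
#' sampling rate across channels, one-second records).
#'
#' @param path EDF file path.
#' @return list with `signal` (channels x samples matrix, physical units),
#'   `samplingRate` and `labels`.
#' @export
readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  nCh <- as.integer(rd(4))
  rdN <- function(width) vapply(seq_len(nCh), function(i) rd(width), "")
  labels <- rdN(16)
  rdN(80); rdN(8)
  physMin <- as.numeric(rdN(8))
  physMax <- as.numeric(rdN(8))
  digMin <- as.numeric(rdN(8))
  digMax <- as.numeric(rdN(8))
  rdN(80)
  spr <- as.integer(rdN(8))
  rdN(32)
  stopifnot(length(unique(spr)) == 1)
  fs <- spr[1] / recDur
  sig <- matrix(0, nCh, nRec * spr[1], dimnames = list(labels, NULL))
  for (r in seq_len(nRec)) {
    raw <- readBin(con, integer(), n = nCh * spr[1], size = 2,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = nCh)
    cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (ch in seq_len(nCh)) {
      sig[ch, cols] <- physMin[ch] + (block[, ch] - digMin[ch]) *
        (physMax[ch] - physMin[ch]) / (digMax[ch] - digMin[ch])
    }
  }
  list(signal = sig, samplingRate = fs, labels = labels)
}
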