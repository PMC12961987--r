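# Minimal EDF (European Data Format) codec: standard 256-byte header plus
# 256 bytes per signal, 16-bit little-endian samples, 1-s data records. The
# true sample count is stashed in the reserved header field ("NS=<n>") so a
# record-padded file trims back to its original length on read. Covers what
# the pipeline needs; not a general-purpose EDF+ implementation.

pad_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width, flag = " ")
}

#' Write a recording to EDF
#'
#' Samples are quantized to 16 bits over each channel's physical range
#' (round-trip error is bounded by half a quantization step). Events are not
#' stored in the EDF; write them with [write_eeg_csv()]'s sidecar or pass
#' them back to [read_eeg()].
#'
#' @param rec a `landemo_eeg`.
#' @param path output path.
#' @return invisible `path`.
#' @export
write_edf <- function(rec, path) {
  X <- rec$samples
  p <- nrow(X); n <- ncol(X)
  spr <- round(rec$rate)           # samples per 1-s record
  n_rec <- ceiling(n / spr)
  pad <- n_rec * spr - n
  if (pad > 0) X <- cbind(X, matrix(0, p, pad))
  pmin_ <- apply(X, 1L, min); pmax_ <- apply(X, 1L, max)
  flat <- pmax_ - pmin_ == 0
  pmax_[flat] <- pmin_[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("landemo", 80), pad_field("synthetic EEG", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + p), 8), pad_field(paste0("NS=", n), 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(p, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, pad_field, "", width = width), collapse = ""),
              con, eos = NULL)
  field(rec$labels, 16)
  field(rep("", p), 80)
  field(rep("uV", p), 8)
  field(formatC(pmin_, digits = 6, format = "g"), 8)
  field(formatC(pmax_, digits = 6, format = "g"), 8)
  field(rep(-32768, p), 8)
  field(rep(32767, p), 8)
  field(rep("", p), 80)
  field(rep(spr, p), 8)
  field(rep("", p), 32)
  scale <- (pmax_ - pmin_) / (32767 - (-32768))
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(p)) {
      dig <- round((X[ch, idx] - pmin_[ch]) / scale[ch]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return list with `samples` (channels x time, physical units), `labels`,
#'   `rate`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                              # header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  p <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(p), function(i) rd(width), "")
  labels <- rdv(16)
  rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  X <- matrix(0, p, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (ch in seq_len(p)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2, endian = "little")
      X[ch, idx] <- (dig - dmin[ch]) * scale[ch] + pmin_[ch]
    }
  }
  m <- regmatches(reserved, regexec("NS=([0-9]+)", reserved))[[1]]
  if (length(m) == 2L) {
    n_true <- as.integer(m[2])
    if (n_true <= ncol(X)) X <- X[, seq_len(n_true), drop = FALSE]
  }
  list(samples = X, labels = labels, rate = spr[1] / dur)
}
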