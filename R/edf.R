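# Minimal European Data Format (EDF) support: fixed-layout ASCII header,
# 16-bit little-endian samples, linear digital-to-physical scaling. Only
# continuous recordings with one common sampling rate are handled, which is
# all the pipeline consumes; EDF+ annotations, BDF and GDF are out of scope.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) abort_io("EDF header field too wide: '%s'", x)
  formatC(x, width = -width, flag = "-")
}

# Render a number into at most `width` ASCII characters.
edf_num <- function(x, width = 8) {
  for (d in 7:1) {
    s <- formatC(x, format = "g", digits = d)
    if (nchar(s) <= width) return(edf_pad(s, width))
  }
  abort_io("cannot format %g into %d EDF header characters", x, width)
}

#' Write a multichannel signal as an EDF file
#'
#' Stores `signal` (channels x samples, physical units) as a standard EDF
#' file with 16-bit samples. Values are scaled linearly into the digital
#' range, so a write/read round trip is exact up to the EDF quantisation
#' step `(physical max - physical min) / 65534`.
#'
#' @param signal numeric matrix, channels x samples.
#' @param fs sampling rate in Hz (positive).
#' @param channel_names character vector, one unique name per row of
#'   `signal` (at most 16 characters each, per the format).
#' @param path output file path.
#' @param subject_id free-text subject identifier stored in the header.
#' @param phys_dim physical dimension label (default microvolts).
#' @return `path`, invisibly.
#' @seealso [read_edf()], [read_recording()]
#' @export
write_edf <- function(signal, fs, channel_names, path,
                      subject_id = "X", phys_dim = "uV") {
  if (!is.matrix(signal) || !is.numeric(signal))
    abort_validation("signal must be a numeric matrix (channels x samples)")
  if (any(!is.finite(signal)))
    abort_validation("signal contains non-finite samples")
  nch <- nrow(signal); ns <- ncol(signal)
  if (length(channel_names) != nch || anyDuplicated(channel_names))
    abort_validation("channel_names must be unique and match nrow(signal)")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    abort_validation("fs must be a positive scalar")

  # One-second records when the length allows it, otherwise a single record.
  if (fs == round(fs) && ns %% fs == 0 && ns > fs) {
    rec_dur <- 1; spr <- as.integer(fs); nrec <- as.integer(ns / fs)
  } else {
    rec_dur <- ns / fs; spr <- as.integer(ns); nrec <- 1L
  }

  pmin <- apply(signal, 1, min); pmax <- apply(signal, 1, max)
  flat <- pmax - pmin <= 0
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32767L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(subject_id, 80),
    edf_pad("cchp", 80),
    edf_pad("01.01.00", 8),
    edf_pad("00.00.00", 8),
    edf_pad(256 + 256 * nch, 8),
    edf_pad("", 44),
    edf_pad(nrec, 8),
    edf_num(rec_dur, 8),
    edf_pad(nch, 4),
    paste(vapply(channel_names, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), nch), collapse = ""),
    paste(rep(edf_pad(phys_dim, 8), nch), collapse = ""),
    paste(vapply(pmin, edf_num, ""), collapse = ""),
    paste(vapply(pmax, edf_num, ""), collapse = ""),
    paste(rep(edf_pad(dmin, 8), nch), collapse = ""),
    paste(rep(edf_pad(dmax, 8), nch), collapse = ""),
    paste(rep(edf_pad("", 80), nch), collapse = ""),
    paste(rep(edf_pad(spr, 8), nch), collapse = ""),
    paste(rep(edf_pad("", 32), nch), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)

  # Header phys limits are re-parsed so scaling matches what a reader sees.
  pmin_r <- as.numeric(vapply(pmin, function(x) edf_num(x), ""))
  pmax_r <- as.numeric(vapply(pmax, function(x) edf_num(x), ""))
  scale <- (dmax - dmin) / (pmax_r - pmin_r)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(nch)) {
      dig <- as.integer(round((signal[ch, idx] - pmin_r[ch]) * scale[ch]) + dmin)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Parses a continuous EDF recording into a list of physical-unit signals.
#' All signals must share one sampling rate (the pipeline treats a file as
#' one multichannel recording).
#'
#' @param path EDF file path.
#' @return list with `signal` (channels x samples matrix), `fs`,
#'   `channel_names` and `subject_id`.
#' @seealso [write_edf()], [read_recording()]
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) abort_io("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8)                                    # version
  subject_id <- rd(80)
  rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  nrec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  if (is.na(nch) || nch < 1) abort_io("malformed EDF header in %s", path)

  field <- function(w) vapply(seq_len(nch), function(i) rd(w), "")
  labels <- field(16); field(80); field(8)
  pmin <- as.numeric(field(8)); pmax <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)
  spr <- as.integer(field(8)); field(32)
  if (hdr_bytes != 256 + 256 * nch)
    abort_io("unexpected EDF header size in %s", path)
  if (length(unique(spr)) != 1)
    abort_io("EDF signals with differing sampling rates are not supported")
  if (rec_dur <= 0) abort_io("non-positive record duration in %s", path)
  fs <- spr[1] / rec_dur

  out <- matrix(0, nch, spr[1] * nrec)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    for (ch in seq_len(nch)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2,
                     signed = TRUE, endian = "little")
      if (length(dig) != spr[ch]) abort_io("truncated EDF data in %s", path)
      out[ch, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        (dig - dmin[ch]) * scale[ch] + pmin[ch]
    }
  }
  list(signal = out, fs = fs, channel_names = labels, subject_id = subject_id)
}
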