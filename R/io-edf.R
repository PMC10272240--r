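# Minimal European Data Format (EDF) reader/writer.
#
# EDF stores an ASCII header (256 bytes + 256 per signal) followed by data
# records of 16-bit little-endian integers. Physical values are recovered by
# the per-signal linear map between (physical min, physical max) and
# (digital min, digital max). The writer scales each channel to its own
# physical range so quantisation error stays well below 0.1 uV for
# EEG-scale data. A single data record spanning the whole recording is
# written, which keeps arbitrary lengths lossless.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) abort(sprintf("EDF header field too long: '%s'", x),
                              "eegtrp_edf_field")
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

write_edf <- function(recording, path) {
  x <- recording$samples
  ns <- nrow(x)
  nsamp <- ncol(x)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) abort(sprintf("cannot open '%s' for writing", path),
                                            "eegtrp_io_error"))
  on.exit(close(con))

  pmin <- apply(x, 1, min)
  pmax <- apply(x, 1, max)
  flat <- pmax - pmin < 1e-9
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32767L
  dmax <- 32767L

  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(recording$subject_id %||% "X", 80),
    edf_pad("eegtrp recording", 80),
    edf_pad("01.01.26", 8),
    edf_pad("00.00.00", 8),
    edf_pad(256 + 256 * ns, 8),
    edf_pad("", 44),
    edf_pad(1, 8),
    edf_num(nsamp / recording$fs, 8),
    edf_pad(ns, 4)
  )
  sig <- paste0(
    paste(vapply(recording$channel_labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(pmin, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(nsamp, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)

  for (i in seq_len(ns)) {
    dig <- round((x[i, ] - pmin[i]) / (pmax[i] - pmin[i]) * (dmax - dmin) + dmin)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path, subject_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                      # version
  patient <- rd(80)
  rd(80); rd(8); rd(8)
  rd(8)                      # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))

  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)          # transducer
  for (i in seq_len(ns)) rd(8)           # physical dimension
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)          # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  out <- matrix(0, nrow = ns, ncol = spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, endian = "little")
      phys <- (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) + pmin[i]
      out[i, (r - 1L) * spr[i] + seq_len(spr[i])] <- phys
    }
  }
  fs <- spr[1] / rec_dur
  list(samples = out, fs = fs, channel_labels = labels,
       subject_id = subject_id %||% patient)
}
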