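# Minimal EDF/EDF+ writer and reader (ASCII header + 16-bit little-endian
# records).  Implemented here because the installed R stack provides no EDF
# support; covers multichannel, mixed-rate recordings with 1 s data records.

edf_pad <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  sprintf(paste0("%-", width, "s"), s)
}

#' Write a recording to an EDF file
#'
#' Signals are quantized to 16 bits over each channel's physical range;
#' data records are 1 s long, so each channel's sampling rate must be a
#' positive integer.  Trailing samples that do not fill a whole record are
#' dropped.
#'
#' @param rec a `signal_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  ch <- names(rec$signals)
  rates <- rec$rates[ch]
  if (any(rates != round(rates) | rates <= 0))
    stop("EDF writer requires integer sampling rates")
  n_rec <- floor(min(vapply(ch, function(nm)
    length(rec$signals[[nm]]) / rates[[nm]], numeric(1))))
  ns <- length(ch)
  pmin_ <- pmax_ <- numeric(ns)
  dig <- vector("list", ns)
  for (i in seq_along(ch)) {
    x <- rec$signals[[ch[i]]][seq_len(n_rec * rates[[i]])]
    lo <- min(x); hi <- max(x)
    if (hi - lo < 1e-6) { hi <- lo + 1; }
    pmin_[i] <- lo; pmax_[i] <- hi
    dig[[i]] <- as.integer(round((x - lo) / (hi - lo) * 65535 - 32768))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80),
    edf_pad("Startdate 01-JAN-2026 X X X", 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(hdr_bytes, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4)),
    con, eos = NULL)
  field <- function(f, w) writeChar(paste0(vapply(seq_len(ns), f,
                                                  character(1)),
                                           collapse = ""), con, eos = NULL)
  field(function(i) edf_pad(ch[i], 16), 16)
  field(function(i) edf_pad("", 80), 80)
  field(function(i) edf_pad(rec$units[[ch[i]]], 8), 8)
  field(function(i) edf_pad(sprintf("%.6g", pmin_[i]), 8), 8)
  field(function(i) edf_pad(sprintf("%.6g", pmax_[i]), 8), 8)
  field(function(i) edf_pad("-32768", 8), 8)
  field(function(i) edf_pad("32767", 8), 8)
  field(function(i) edf_pad("", 80), 80)
  field(function(i) edf_pad(rates[[i]], 8), 8)
  field(function(i) edf_pad("", 32), 32)
  for (r in seq_len(n_rec)) {
    for (i in seq_along(ch)) {
      s0 <- (r - 1) * rates[[i]] + 1
      writeBin(dig[[i]][s0:(s0 + rates[[i]] - 1)], con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a signal recording
#'
#' Channel roles are mapped from labels: labels containing "EOG" become
#' EOG, "ECG"/"EKG" become ECG, everything else EEG.  Per-channel sampling
#' rates are preserved.
#'
#' @param path EDF file.
#' @return a `signal_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- rdv(16); rdv(80); units <- rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  sig <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                   endian = "little")
      sig[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <-
        (d - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i]) +
        pmin_[i]
    }
  }
  names(sig) <- labels
  roles <- ifelse(grepl("EOG", labels, ignore.case = TRUE), "EOG",
                  ifelse(grepl("E[CK]G", labels, ignore.case = TRUE),
                         "ECG", "EEG"))
  signal_recording(sig,
                   rates = stats::setNames(spr / rec_dur, labels),
                   roles = stats::setNames(roles, labels),
                   units = stats::setNames(units, labels))
}

#' Read a recording and validate channel roles
#'
#' @param path EDF/EDF+ file with labelled channels.
#' @param require roles that must be present (default EEG and ECG).
#' @return a `signal_recording`.
#' @export
read_recording <- function(path, require = c("EEG", "ECG")) {
  rec <- read_edf(path)
  missing <- setdiff(require, unique(rec$roles))
  if (length(missing))
    stop("missing channel roles ", paste(missing, collapse = ", "),
         "; found labels: ", paste(names(rec$signals), collapse = ", "))
  rec
}
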