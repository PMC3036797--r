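# Minimal EDF (European Data Format) binary I/O.
# Only the plain EDF feature set is supported: 16-bit samples, ASCII headers,
# no EDF+ annotation signals. Amplitudes are stored and returned in uV.

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width, flag = "-")
}

edf_num <- function(x, width = 8) {
  # shortest decimal representation that fits the fixed-width ASCII field
  for (d in seq(10, 1)) {
    s <- formatC(x, digits = d, format = "g", width = -1)
    if (nchar(s) <= width) return(s)
  }
  stop("cannot represent ", x, " in an EDF numeric field")
}

#' Write a recording to an EDF file
#'
#' Writes one EDF signal per channel with physical units uV and 16-bit
#' digital samples scaled to the channel's amplitude range. The whole
#' recording is stored as a single data record.
#'
#' @param recording an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  x <- recording$samples
  if (nrow(x) == 0) stop("cannot write a zero-length recording")
  if (!all(is.finite(x))) stop("recording contains non-finite samples")
  ns <- ncol(x)
  n <- nrow(x)
  dig_min <- -32768L; dig_max <- 32767L

  pmin_str <- pmax_str <- character(ns)
  for (j in seq_len(ns)) {
    m <- max(abs(x[, j]), 1e-6)
    pmax_str[j] <- edf_num(m)
    pmin_str[j] <- edf_num(-as.numeric(pmax_str[j]))
  }
  pmax <- as.numeric(pmax_str); pmin <- as.numeric(pmin_str)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(edf_field("0", 8))
  wr(edf_field(recording$patient_id, 80))
  wr(edf_field("neoseize", 80))
  wr(edf_field("01.01.00", 8))
  wr(edf_field("00.00.00", 8))
  wr(edf_field(256L * (ns + 1L), 8))
  wr(edf_field("", 44))
  wr(edf_field(1L, 8))                       # one data record
  wr(edf_field(edf_num(n / recording$fs), 8))
  wr(edf_field(ns, 4))
  for (lab in recording$channels) wr(edf_field(lab, 16))
  for (j in seq_len(ns)) wr(edf_field("", 80))
  for (j in seq_len(ns)) wr(edf_field("uV", 8))
  for (j in seq_len(ns)) wr(edf_field(pmin_str[j], 8))
  for (j in seq_len(ns)) wr(edf_field(pmax_str[j], 8))
  for (j in seq_len(ns)) wr(edf_field(dig_min, 8))
  for (j in seq_len(ns)) wr(edf_field(dig_max, 8))
  for (j in seq_len(ns)) wr(edf_field("", 80))
  for (j in seq_len(ns)) wr(edf_field(n, 8))
  for (j in seq_len(ns)) wr(edf_field("", 32))
  for (j in seq_len(ns)) {
    scale <- (pmax[j] - pmin[j]) / (dig_max - dig_min)
    dig <- round((x[, j] - pmin[j]) / scale) + dig_min
    dig <- pmin.int(pmax.int(dig, dig_min), dig_max)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(width) {
    s <- readChar(con, width, useBytes = TRUE)
    if (length(s) == 0 || nchar(s, type = "bytes") < width)
      stop("not a readable EDF file: truncated header")
    trimws(s)
  }
  version <- rd(8)
  patient <- rd(80); rd(80); rd(8); rd(8)
  header_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_records <- suppressWarnings(as.integer(rd(8)))
  record_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (is.na(ns) || ns < 1 || is.na(n_records) || is.na(record_dur))
    stop("not a readable EDF file: malformed header")
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16); rdv(80); units <- rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  nsamp <- as.integer(rdv(8))
  rdv(32)
  list(patient = patient, header_bytes = header_bytes, n_records = n_records,
       record_dur = record_dur, ns = ns, labels = labels, units = units,
       pmin = pmin, pmax = pmax, dmin = dmin, dmax = dmax, nsamp = nsamp)
}

#' Read an EDF file as an EEG recording
#'
#' Reads all signals of an EDF file and returns them in uV. When the file
#' stores referential electrodes (e.g. `F4`, `C4`, `O2`), every derivation of
#' the default neonatal bipolar montage whose two electrodes are both present
#' is formed (first minus second electrode); otherwise the channels are
#' returned as stored.
#'
#' @param path path to an EDF file.
#' @param montage bipolar derivations to form from referential electrodes;
#'   default [neonatal_montage()].
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path, montage = neonatal_montage()) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  if (any(is.na(h$nsamp)) || any(h$nsamp < 1))
    stop("not a readable EDF file: bad samples-per-record")
  sig <- vector("list", h$ns)
  for (j in seq_len(h$ns)) sig[[j]] <- numeric(h$n_records * h$nsamp[j])
  for (r in seq_len(h$n_records)) {
    for (j in seq_len(h$ns)) {
      raw <- readBin(con, "integer", n = h$nsamp[j], size = 2,
                     endian = "little", signed = TRUE)
      if (length(raw) < h$nsamp[j]) stop("EDF file truncated mid-record")
      scale <- (h$pmax[j] - h$pmin[j]) / (h$dmax[j] - h$dmin[j])
      sig[[j]][(r - 1) * h$nsamp[j] + seq_len(h$nsamp[j])] <-
        (raw - h$dmin[j]) * scale + h$pmin[j]
    }
  }
  labels <- canonical_channel(sub("^EEG ", "", h$labels))
  fs_all <- h$nsamp / h$record_dur

  if (!any(grepl("-", labels, fixed = TRUE))) {
    # referential storage: derive the bipolar montage where possible
    pairs <- strsplit(montage, "-", fixed = TRUE)
    derivable <- vapply(pairs, function(p) all(p %in% labels), TRUE)
    if (any(derivable)) {
      used <- unique(unlist(pairs[derivable]))
      if (length(unique(fs_all[match(used, labels)])) > 1)
        stop("electrodes of the requested montage have mismatched sampling rates")
      mat <- vapply(pairs[derivable], function(p)
        sig[[match(p[1], labels)]] - sig[[match(p[2], labels)]],
        numeric(length(sig[[match(pairs[derivable][[1]][1], labels)]])))
      return(eeg_recording(mat, fs_all[match(used[1], labels)],
                           montage[derivable], h$patient))
    }
  }
  if (length(unique(fs_all)) > 1)
    stop("signals have mismatched sampling rates; cannot form a recording")
  eeg_recording(do.call(cbind, sig), fs_all[1], labels, h$patient)
}
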