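#' Remove the mains component with a zero-phase notch filter
#'
#' A second-order IIR notch (quality factor `q`) centred on the mains
#' frequency, applied forward and backward so the net filter has zero phase.
#' The EEG band of interest (below 13 Hz) is left untouched to within 1%.
#'
#' @param recording an [eeg_recording()].
#' @param mains_hz mains frequency in Hz (default 50).
#' @param q notch quality factor; bandwidth = `mains_hz / q` (default 30).
#' @return filtered [eeg_recording()].
#' @export
notch_filter <- function(recording, mains_hz = 50, q = 30) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (fs <= 2 * mains_hz)
    stop(sprintf("sampling rate %g Hz too low to notch %g Hz", fs, mains_hz))
  w0 <- 2 * pi * mains_hz / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  out <- recording
  for (j in seq_len(ncol(out$samples)))
    out$samples[, j] <- signal::filtfilt(b, a, recording$samples[, j])
  out
}

# Linear-phase Kaiser-window FIR low-pass, returned as (odd-length) taps.
# Delay-compensated application gives an exactly zero-phase filter.
design_lowpass <- function(fs, pass_hz, stop_hz, atten_db = 60) {
  beta <- 0.1102 * (atten_db - 8.7)
  dw <- 2 * pi * (stop_hz - pass_hz) / fs
  n <- ceiling((atten_db - 7.95) / (2.285 * dw))
  if (n %% 2 == 1) n <- n + 1                    # even order -> odd taps
  wc <- ((pass_hz + stop_hz) / 2) / (fs / 2)
  signal::fir1(n, wc, type = "low", window = signal::kaiser(n + 1, beta))
}

# FFT-based zero-phase application of a symmetric FIR filter
apply_fir_zerophase <- function(x, b) {
  n <- length(x); delay <- (length(b) - 1) / 2
  y <- stats::convolve(x, rev(b), type = "open")
  y[delay + seq_len(n)]
}

#' Downsample a recording with an anti-aliasing filter
#'
#' Low-pass filters each channel with a zero-phase FIR whose passband edge is
#' `cutoff_hz` (default 12.8 Hz, stopband reached 1.6 Hz above it at >= 60 dB)
#' and keeps every `fs/target_fs`-th sample. The downsampling factor must be
#' an integer.
#'
#' @param recording an [eeg_recording()] (typically 256 Hz).
#' @param target_fs output sampling rate in Hz (default 32).
#' @param cutoff_hz anti-aliasing passband edge in Hz (default 12.8).
#' @return an [eeg_recording()] at `target_fs` Hz with `ceiling(n/factor)`
#'   samples per channel.
#' @export
downsample_eeg <- function(recording, target_fs = 32, cutoff_hz = 12.8) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (fs %% target_fs != 0)
    stop(sprintf("sampling rate %g Hz is not an integer multiple of %g Hz",
                 fs, target_fs))
  factor <- fs / target_fs
  if (factor == 1) return(recording)
  b <- design_lowpass(fs, cutoff_hz, cutoff_hz + 1.6)
  keep <- seq(1, nrow(recording$samples), by = factor)
  out_mat <- matrix(0, length(keep), ncol(recording$samples))
  for (j in seq_len(ncol(recording$samples)))
    out_mat[, j] <- apply_fir_zerophase(recording$samples[, j], b)[keep]
  eeg_recording(out_mat, target_fs, recording$channels,
                recording$patient_id, recording$start_time)
}

#' Segment a recording into overlapping analysis epochs
#'
#' Splits each channel into epochs of `epoch_len_s` seconds advancing by
#' `hop_s` seconds (defaults 8 s / 4 s: 50% overlap). Only complete epochs
#' are kept, so a record of `T` seconds yields `floor((T - 8)/4) + 1` epochs
#' starting at 0, 4, 8, ... seconds.
#'
#' @param recording an [eeg_recording()] (normally already at 32 Hz).
#' @param epoch_len_s epoch length in seconds (default 8).
#' @param hop_s hop between successive epoch starts in seconds (default 4).
#' @return object of class `epoch_grid`: array `data` of dimension
#'   (samples per epoch, n epochs, n channels), `start_times_s`, `fs`,
#'   `epoch_len_s`, `hop_s`, `channels`, `patient_id`. A record shorter than
#'   one epoch gives an empty grid with a warning.
#' @export
segment_epochs <- function(recording, epoch_len_s = 8, hop_s = 4) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  len <- round(epoch_len_s * fs)
  hop <- round(hop_s * fs)
  n <- nrow(recording$samples)
  n_epochs <- if (n < len) 0L else (n - len) %/% hop + 1L
  if (n_epochs == 0L)
    warning(sprintf("record (%.1f s) shorter than one %g s epoch: empty grid",
                    n / fs, epoch_len_s))
  data <- array(0, dim = c(len, n_epochs, ncol(recording$samples)),
                dimnames = list(NULL, NULL, recording$channels))
  for (e in seq_len(n_epochs)) {
    idx <- (e - 1L) * hop + seq_len(len)
    data[, e, ] <- recording$samples[idx, , drop = FALSE]
  }
  structure(
    list(data = data, start_times_s = (seq_len(n_epochs) - 1) * hop_s,
         fs = fs, epoch_len_s = epoch_len_s, hop_s = hop_s,
         channels = recording$channels, patient_id = recording$patient_id),
    class = "epoch_grid")
}

#' @export
print.epoch_grid <- function(x, ...) {
  cat(sprintf("<epoch_grid> %d epoch(s) x %d channel(s), %g s / %g s hop @ %g Hz\n",
              dim(x$data)[2], dim(x$data)[3], x$epoch_len_s, x$hop_s, x$fs))
  invisible(x)
}

#' Seizure training-epoch counting convention
#'
#' The number of seizure training epochs contributed by per-channel seizure
#' annotations, counted as annotated duration divided by the hop: with 2 min
#' of annotated seizure per patient, a 4 s hop and on average 4 annotated
#' channels, 16 patients contribute `16 * (120/4) * 4 = 1920` epochs.
#'
#' @param annotated_s annotated seizure duration per patient in seconds.
#' @param hop_s epoch hop in seconds.
#' @param n_patients number of patients.
#' @param mean_channels mean number of annotated channels per seizure.
#' @return expected number of seizure training epochs.
#' @export
training_epoch_count <- function(annotated_s, hop_s = 4, n_patients = 1,
                                 mean_channels = 1) {
  if (hop_s <= 0) stop("hop_s must be positive")
  n_patients * (annotated_s / hop_s) * mean_channels
}

#' Label epochs per channel from reference annotations
#'
#' An epoch on a given channel is labelled seizure (+1) when at least
#' `overlap_frac` of its span intersects a reference seizure event on that
#' channel, and non-seizure (-1) otherwise. Intervals are half-open.
#'
#' @param grid an `epoch_grid` from [segment_epochs()].
#' @param annotations an [annotation_set()] for the same patient.
#' @param overlap_frac minimum overlapping fraction of the epoch span needed
#'   for a seizure label (default 0.5).
#' @return integer matrix (n epochs x n channels) of +1/-1 labels.
#' @export
label_epochs <- function(grid, annotations, overlap_frac = 0.5) {
  stopifnot(inherits(grid, "epoch_grid"))
  n_epochs <- dim(grid$data)[2]
  labels <- matrix(-1L, n_epochs, length(grid$channels),
                   dimnames = list(NULL, grid$channels))
  if (n_epochs == 0 || is.null(annotations) || nrow(annotations$events) == 0)
    return(labels)
  starts <- grid$start_times_s
  ends <- starts + grid$epoch_len_s
  overlap <- matrix(0, n_epochs, length(grid$channels))
  for (i in seq_len(nrow(annotations$events))) {
    ev <- annotations$events[i, ]
    chs <- event_channels(ev$channels, grid$channels)
    if (!length(chs)) next
    ol <- pmax(0, pmin(ends, ev$end_s) - pmax(starts, ev$start_s))
    overlap[, match(chs, grid$channels)] <-
      overlap[, match(chs, grid$channels), drop = FALSE] + ol
  }
  labels[overlap >= overlap_frac * grid$epoch_len_s] <- 1L
  labels
}
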