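# Per-epoch feature extraction: 28 frequency-domain, 23 time-domain and 4
# information-theory features (55 in total) computed from each 8 s, 256-sample
# epoch at 32 Hz.

#' Canonical ordered feature names
#'
#' The frozen order of the 55 per-epoch features: 28 frequency-domain
#' (total power 0-12 Hz, peak frequency, spectral edge frequencies 80/90/95%,
#' eleven 2 Hz-wide sub-band powers 0-2 ... 10-12 Hz, the same sub-bands
#' normalized by total power, wavelet energy), 23 time-domain (curve length,
#' number of extrema, RMS amplitude, Hjorth activity/mobility/complexity,
#' zero crossings of the epoch and its first and second differences, Burg AR
#' prediction-error variance for model orders 1-9, skewness, kurtosis,
#' nonlinear energy, variance of first and second differences) and 4
#' information-theory features (Shannon entropy, SVD entropy, Fisher
#' information, spectral entropy).
#'
#' @return character vector of length 55.
#' @export
feature_names <- function() {
  bands <- paste0(0:10, "_", 2:12)
  c("total_power", "peak_freq", "sef80", "sef90", "sef95",
    paste0("bp_", bands), paste0("nbp_", bands), "wavelet_energy",
    "curve_length", "n_extrema", "rms",
    "hjorth_activity", "hjorth_mobility", "hjorth_complexity",
    "zero_crossings", "zero_crossings_d1", "zero_crossings_d2",
    paste0("ar_err_", 1:9), "skewness", "kurtosis", "nonlinear_energy",
    "var_d1", "var_d2",
    "shannon_entropy", "svd_entropy", "fisher_information", "spectral_entropy")
}

# general one-sided periodogram that conserves power:
# sum(power) == mean(x^2) (Parseval)
periodogram <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  half <- floor(n / 2) + 1L
  p <- (Mod(X[seq_len(half)])^2) / n^2
  if (n %% 2 == 0) p[2:(half - 1)] <- 2 * p[2:(half - 1)]
  else p[2:half] <- 2 * p[2:half]
  list(frequencies = (seq_len(half) - 1) * fs / n, power = p)
}

#' Power spectral density of one epoch
#'
#' Rectangular-window periodogram from a 256-point FFT of the 256-sample
#' epoch, one-sided on the 0.125 Hz grid from 0 to 16 Hz. The PSD conserves
#' power: the bin sum equals the mean square of the samples.
#'
#' @param epoch numeric vector of exactly 256 samples.
#' @param fs sampling rate in Hz (default 32).
#' @return list with `frequencies` (Hz) and nonnegative `power` per bin.
#' @export
compute_psd <- function(epoch, fs = 32) {
  if (length(epoch) != 256)
    stop("epoch must have exactly 256 samples, got ", length(epoch))
  periodogram(epoch, fs)
}

band_power <- function(psd, lo, hi) {
  sum(psd$power[psd$frequencies >= lo & psd$frequencies <= hi])
}

spectral_edge <- function(psd, frac, f_max = 12) {
  in_band <- psd$frequencies <= f_max
  p <- psd$power[in_band]
  total <- sum(p)
  if (total <= 0) return(0)
  idx <- which(cumsum(p) >= frac * total)[1]
  psd$frequencies[in_band][idx]
}

#' Daubechies-4 wavelet energy of the 1-2 Hz detail band
#'
#' Decomposes the epoch with an 8-tap Daubechies-4 discrete wavelet transform
#' (periodic extension) and returns the sum of squared coefficients of the
#' detail band whose nominal range at 32 Hz is 1-2 Hz (fourth decomposition
#' level).
#'
#' @param epoch numeric vector (length a multiple of 16).
#' @param level detail level whose energy is returned (default 4).
#' @return scalar energy.
#' @export
wavelet_energy <- function(epoch, level = 4) {
  # db4 (four vanishing moments) orthonormal decomposition low-pass filter
  lo <- c(-0.010597401784997278, 0.032883011666982945, 0.030841381835986965,
          -0.187034811718881140, -0.027983769416983849, 0.630880767929590400,
          0.714846570552541500, 0.230377813308855230)
  hi <- rev(lo) * c(1, -1)                      # quadrature mirror filter
  a <- epoch
  for (l in seq_len(level)) {
    n <- length(a)
    # periodic convolution then dyadic downsampling
    ext <- c(a, a[((seq_len(length(lo) - 1) - 1) %% n) + 1])
    conv_lo <- stats::filter(ext, lo, sides = 1)
    conv_hi <- stats::filter(ext, hi, sides = 1)
    keep <- seq(length(lo), n + length(lo) - 1, by = 2)
    d <- conv_hi[keep]
    a <- as.numeric(conv_lo[keep])
    if (l == level) return(sum(d^2))
  }
}

#' Frequency-domain features of one epoch
#'
#' @param psd PSD from [compute_psd()].
#' @param wavelet_en wavelet energy of the same epoch from [wavelet_energy()].
#' @return named numeric vector of 28 values: total power in 0-12 Hz, peak
#'   frequency (DC excluded), SEF 80/90/95%, eleven 2 Hz sub-band powers,
#'   eleven normalized sub-band powers, wavelet energy. With zero in-band
#'   power the normalized sub-bands and SEFs are defined as 0.
#' @export
frequency_features <- function(psd, wavelet_en) {
  total <- band_power(psd, 0, 12)
  nz <- psd$frequencies > 0 & psd$frequencies <= 12
  peak <- if (any(psd$power[nz] > 0))
    psd$frequencies[nz][which.max(psd$power[nz])] else 0
  sef <- vapply(c(0.80, 0.90, 0.95), function(fr) spectral_edge(psd, fr), 0)
  bp <- vapply(0:10, function(lo) band_power(psd, lo, lo + 2), 0)
  nbp <- if (total > 0) bp / total else rep(0, 11)
  out <- c(total, peak, sef, bp, nbp, wavelet_en)
  names(out) <- feature_names()[1:28]
  out
}

zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0)
  sum(diff(s) != 0)
}

burg_errors <- function(x, max_order = 9) {
  v <- mean((x - mean(x))^2)
  if (v <= .Machine$double.eps * max(1, mean(x^2))) return(rep(0, max_order))
  fit <- tryCatch(stats::ar.burg(x, aic = FALSE, order.max = max_order,
                                 demean = TRUE),
                  error = function(e) NULL)
  if (is.null(fit)) return(rep(0, max_order))
  k <- drop(fit$partialacf)
  v * cumprod(1 - k^2)
}

#' Time-domain features of one epoch
#'
#' @param epoch numeric vector of 256 samples.
#' @return named numeric vector of 23 values: curve length, number of local
#'   extrema, RMS amplitude, Hjorth activity/mobility/complexity, zero
#'   crossings of the raw epoch and its first and second differences, Burg AR
#'   final prediction-error variances for orders 1-9, skewness, kurtosis,
#'   nonlinear (Teager) energy, and variances of the first and second
#'   differences. Ratios undefined for a constant epoch are returned as 0.
#' @export
time_features <- function(epoch) {
  d1 <- diff(epoch)
  d2 <- diff(d1)
  n <- length(epoch)
  curve_length <- sum(abs(d1))
  s <- sign(d1); s <- s[s != 0]
  n_extrema <- if (length(s) < 2) 0 else sum(diff(s) != 0)
  rms <- sqrt(mean(epoch^2))
  v0 <- stats::var(epoch); v1 <- stats::var(d1); v2 <- stats::var(d2)
  mobility <- if (v0 > 0) sqrt(v1 / v0) else 0
  mob_d1 <- if (v1 > 0) sqrt(v2 / v1) else 0
  complexity <- if (mobility > 0) mob_d1 / mobility else 0
  sk <- if (v0 > 0) e1071::skewness(epoch) else 0
  ku <- if (v0 > 0) e1071::kurtosis(epoch) else 0
  teager <- mean(epoch[2:(n - 1)]^2 - epoch[1:(n - 2)] * epoch[3:n])
  out <- c(curve_length, n_extrema, rms, v0, mobility, complexity,
           zero_crossings(epoch), zero_crossings(d1), zero_crossings(d2),
           burg_errors(epoch), sk, ku, teager, v1, v2)
  names(out) <- feature_names()[29:51]
  out
}

shannon_entropy <- function(x, n_bins = 10, base = exp(1)) {
  r <- range(x)
  if (r[2] <= r[1]) return(0)
  counts <- tabulate(
    pmin(n_bins, findInterval(x, seq(r[1], r[2], length.out = n_bins + 1),
                              rightmost.closed = TRUE)),
    nbins = n_bins)
  p <- counts[counts > 0] / length(x)
  -sum(p * log(p)) / log(base)
}

normalized_singular_values <- function(x, dim = 20, delay = 1) {
  m <- length(x) - (dim - 1) * delay
  emb <- vapply(seq_len(dim), function(j) x[(j - 1) * delay + seq_len(m)],
                numeric(m))
  sv <- svd(emb, nu = 0, nv = 0)$d
  if (sum(sv) <= 0) return(rep(0, dim))
  sv / sum(sv)
}

#' Information-theory features of one epoch
#'
#' Shannon entropy of the amplitude histogram (10 equal-width bins, natural
#' log, empty bins skipped), entropy of the normalized singular values of the
#' delay-embedding matrix (dimension 20, delay 1), Fisher information of the
#' same singular-value distribution, and Shannon entropy of the PSD
#' normalized over 0-12 Hz.
#'
#' @param epoch numeric vector of 256 samples.
#' @param psd PSD of the epoch from [compute_psd()].
#' @return named numeric vector of 4 values.
#' @export
info_features <- function(epoch, psd) {
  s <- normalized_singular_values(epoch)
  s_pos <- s[s > 0]
  svd_ent <- if (length(s_pos)) -sum(s_pos * log(s_pos)) else 0
  fisher <- {
    num <- diff(s)^2
    den <- s[-length(s)]
    sum(ifelse(den > 0, num / den, 0))
  }
  in_band <- psd$frequencies <= 12
  p <- psd$power[in_band]
  spec_ent <- if (sum(p) > 0) {
    q <- p[p > 0] / sum(p)
    -sum(q * log(q))
  } else 0
  out <- c(shannon_entropy(epoch), svd_ent, fisher, spec_ent)
  names(out) <- feature_names()[52:55]
  out
}

#' Extract the full 55-feature vector from one epoch
#'
#' @param epoch numeric vector of exactly 256 samples (8 s at 32 Hz).
#' @param fs sampling rate in Hz (default 32).
#' @return named numeric vector of length 55 in the [feature_names()] order.
#' @export
extract_features <- function(epoch, fs = 32) {
  psd <- compute_psd(epoch, fs)
  c(frequency_features(psd, wavelet_energy(epoch)),
    time_features(epoch),
    info_features(epoch, psd))
}

#' Feature matrix for every epoch/channel of a grid
#'
#' @param grid an `epoch_grid` from [segment_epochs()].
#' @return list with `features` (one row per epoch x channel, 55 columns),
#'   and provenance vectors `channel` and `start_s` aligned to the rows.
#' @export
extract_grid_features <- function(grid) {
  stopifnot(inherits(grid, "epoch_grid"))
  n_epochs <- dim(grid$data)[2]
  n_ch <- dim(grid$data)[3]
  feats <- matrix(NA_real_, n_epochs * n_ch, 55,
                  dimnames = list(NULL, feature_names()))
  channel <- character(n_epochs * n_ch)
  start_s <- numeric(n_epochs * n_ch)
  row <- 0L
  for (ch in seq_len(n_ch)) {
    for (e in seq_len(n_epochs)) {
      row <- row + 1L
      feats[row, ] <- extract_features(grid$data[, e, ch], grid$fs)
      channel[row] <- grid$channels[ch]
      start_s[row] <- grid$start_times_s[e]
    }
  }
  list(features = feats, channel = channel, start_s = start_s)
}
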