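# Post-processing of per-epoch probabilities into fused binary decisions:
# central moving average, thresholding, OR fusion across channels, collar.

#' Central moving-average filter
#'
#' `y[i] = mean(x[(i-N):(i+N)])` with `order = 2N + 1` points. At the series
#' edges the window is truncated to the available samples and renormalized,
#' so constant series stay constant everywhere. With the default 4 s epoch
#' hop, an order-15 filter spans `(15 - 1) * 4 + 8 = 64` seconds of signal.
#'
#' @param x numeric vector (per-channel probability sequence).
#' @param order odd filter order (number of points; default 15).
#' @return filtered vector, bounded by `range(x)`.
#' @export
moving_average <- function(x, order = 15) {
  if (order < 1 || order %% 2 == 0) stop("`order` must be an odd integer >= 1")
  n <- length(x)
  if (n == 0) return(x)
  half <- (order - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Threshold a probability series into binary decisions
#'
#' @param x numeric vector or matrix (columns = channels) of probabilities.
#' @param threshold decision threshold in `[0, 1]`; values `>= threshold`
#'   become 1 (ties count as seizure).
#' @return integer vector/matrix of 0/1 decisions.
#' @export
threshold_decisions <- function(x, threshold) {
  if (length(threshold) != 1 || is.na(threshold) ||
      threshold < 0 || threshold > 1)
    stop("`threshold` must be a single value in [0, 1]")
  d <- (x >= threshold) + 0L
  d
}

#' Fuse per-channel binary decisions with a logical OR
#'
#' @param decisions integer matrix (epochs x channels) of 0/1 decisions, or a
#'   list of equal-length vectors.
#' @return integer vector: 1 where any channel is 1.
#' @export
fuse_channels <- function(decisions) {
  if (is.list(decisions)) {
    if (length(unique(lengths(decisions))) != 1)
      stop("per-channel decision series have different lengths")
    decisions <- do.call(cbind, decisions)
  }
  as.integer(rowSums(decisions) > 0)
}

#' Fuse probability channels with MAX then threshold
#'
#' Thresholding the elementwise maximum across channels; identical to
#' thresholding each channel and OR-fusing the binary decisions.
#'
#' @param probabilities numeric matrix (epochs x channels) or list of
#'   equal-length vectors.
#' @param threshold decision threshold in `[0, 1]`.
#' @return integer vector of fused 0/1 decisions.
#' @export
fuse_max <- function(probabilities, threshold) {
  if (is.list(probabilities)) {
    if (length(unique(lengths(probabilities))) != 1)
      stop("per-channel probability series have different lengths")
    probabilities <- do.call(cbind, probabilities)
  }
  threshold_decisions(apply(probabilities, 1, max), threshold)
}

#' Extend positive decisions with a collar
#'
#' Every maximal run of seizure decisions is extended by `collar_s` seconds
#' on each side (rounded to whole epochs at the given hop, with a warning if
#' rounding is needed), clipped to the series bounds; runs that come to
#' overlap merge.
#'
#' @param decisions integer vector of 0/1 decisions.
#' @param collar_s collar duration per side in seconds (default 40).
#' @param hop_s epoch hop in seconds (default 4).
#' @return integer vector of collared 0/1 decisions.
#' @export
apply_collar <- function(decisions, collar_s = 40, hop_s = 4) {
  if (collar_s < 0) stop("`collar_s` must be >= 0")
  k <- collar_s / hop_s
  if (abs(k - round(k)) > 1e-9) {
    warning(sprintf("collar %g s is not a multiple of the %g s hop; rounded",
                    collar_s, hop_s))
  }
  k <- as.integer(round(k))
  n <- length(decisions)
  if (k == 0 || n == 0 || !any(decisions == 1)) return(decisions)
  out <- integer(n)
  pos <- which(decisions == 1)
  runs_start <- pos[c(TRUE, diff(pos) > 1)]
  runs_end <- pos[c(diff(pos) > 1, TRUE)]
  for (i in seq_along(runs_start))
    out[max(1, runs_start[i] - k):min(n, runs_end[i] + k)] <- 1L
  out
}

#' Full post-processing chain for one recording
#'
#' Applies, in order: Platt sigmoid (already done upstream), per-channel
#' moving average, per-channel thresholding, OR fusion across channels, and
#' the collar.
#'
#' @param probabilities numeric matrix (epochs x channels) of per-epoch
#'   seizure probabilities.
#' @param threshold decision threshold.
#' @param maf_order moving-average order (default 15).
#' @param collar_s collar per side in seconds (default 40).
#' @param hop_s epoch hop in seconds (default 4).
#' @return integer vector of fused, collared 0/1 decisions.
#' @export
postprocess_probabilities <- function(probabilities, threshold,
                                      maf_order = 15, collar_s = 40,
                                      hop_s = 4) {
  smoothed <- apply(probabilities, 2, moving_average, order = maf_order)
  if (is.vector(smoothed)) smoothed <- matrix(smoothed, ncol = ncol(probabilities))
  fused <- fuse_channels(threshold_decisions(smoothed, threshold))
  apply_collar(fused, collar_s, hop_s)
}
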