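# Event-based scoring: good detection rate (GDR), false detections per hour
# (FD/h), threshold-sweep performance curves, duration-binned miss analysis
# and dataset summary arithmetic.

#' Join consecutive positive decisions into events
#'
#' Each maximal run of seizure decisions becomes one interval from the start
#' of its first epoch to the end (start + epoch length) of its last epoch;
#' overlapping intervals (epochs overlap by construction) merge.
#'
#' @param decisions integer vector of 0/1 decisions.
#' @param hop_s epoch hop in seconds (default 4).
#' @param epoch_len_s epoch length in seconds (default 8).
#' @param total_duration_h record duration in hours; default inferred from
#'   the series length.
#' @return an [event_list()].
#' @export
decisions_to_events <- function(decisions, hop_s = 4, epoch_len_s = 8,
                                total_duration_h = NULL) {
  n <- length(decisions)
  if (is.null(total_duration_h))
    total_duration_h <- ((n - 1) * hop_s + epoch_len_s) / 3600
  pos <- which(decisions == 1)
  if (!length(pos))
    return(structure(list(events = data.frame(start_s = numeric(0),
                                              end_s = numeric(0)),
                          total_duration_h = total_duration_h),
                     class = "event_list"))
  runs_start <- pos[c(TRUE, diff(pos) > 1)]
  runs_end <- pos[c(diff(pos) > 1, TRUE)]
  event_list((runs_start - 1) * hop_s, (runs_end - 1) * hop_s + epoch_len_s,
             total_duration_h)
}

# overlap length of [a1,a2) with each interval in (b1,b2)
overlaps_any <- function(a1, a2, b1, b2) {
  any(pmin(a2, b2) > pmax(a1, b1))
}

#' Good detection rate
#'
#' Percentage of reference seizure events overlapped (any nonempty
#' intersection of the half-open intervals) by at least one detected event.
#' A detection spanning several reference seizures counts all of them as
#' detected. With no reference events the rate is undefined and `NA` is
#' returned with a warning.
#'
#' @param reference [event_list()] of expert-labelled seizures.
#' @param detected [event_list()] of detector events.
#' @return percentage in `[0, 100]`, or `NA` if `reference` is empty.
#' @export
gdr <- function(reference, detected) {
  nr <- nrow(reference$events)
  if (nr == 0) {
    warning("no reference events: GDR undefined")
    return(NA_real_)
  }
  hit <- vapply(seq_len(nr), function(i)
    overlaps_any(reference$events$start_s[i], reference$events$end_s[i],
                 detected$events$start_s, detected$events$end_s), TRUE)
  100 * sum(hit) / nr
}

#' False detections per hour
#'
#' Number of detected events having zero overlap with every reference
#' seizure, divided by the record duration in hours.
#'
#' @param detected [event_list()] of detector events.
#' @param reference [event_list()] of expert-labelled seizures.
#' @param hours record duration in hours; defaults to
#'   `detected$total_duration_h`.
#' @return false detections per hour (>= 0).
#' @export
fd_per_hour <- function(detected, reference, hours = detected$total_duration_h) {
  if (is.null(hours) || !is.finite(hours) || hours <= 0)
    stop("`hours` must be positive")
  nd <- nrow(detected$events)
  if (nd == 0) return(0)
  false <- vapply(seq_len(nd), function(i)
    !overlaps_any(detected$events$start_s[i], detected$events$end_s[i],
                  reference$events$start_s, reference$events$end_s), TRUE)
  sum(false) / hours
}

#' Sweep the decision threshold to obtain a performance curve
#'
#' Re-runs the full post-processing chain (moving average, threshold, OR
#' fusion, collar, event formation) for every threshold in the grid and
#' scores each operating point against the reference events. The moving
#' average is threshold-independent and computed once.
#'
#' @param probabilities numeric matrix (epochs x channels) of per-epoch
#'   seizure probabilities for one recording.
#' @param reference [event_list()] of labelled seizures for the recording.
#' @param thresholds threshold grid in `[0, 1]` (default `seq(0, 1, 0.01)`).
#' @param maf_order,collar_s,hop_s,epoch_len_s post-processing parameters.
#' @return data.frame with columns `threshold`, `gdr_pct`, `fd_per_h`.
#' @export
performance_curve <- function(probabilities, reference,
                              thresholds = seq(0, 1, by = 0.01),
                              maf_order = 15, collar_s = 40, hop_s = 4,
                              epoch_len_s = 8) {
  if (!length(thresholds)) stop("threshold grid is empty")
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must lie in [0, 1]")
  smoothed <- apply(probabilities, 2, moving_average, order = maf_order)
  if (is.vector(smoothed))
    smoothed <- matrix(smoothed, ncol = ncol(probabilities))
  hours <- ((nrow(probabilities) - 1) * hop_s + epoch_len_s) / 3600
  n_ref <- nrow(reference$events)
  out <- data.frame(threshold = thresholds, gdr_pct = NA_real_,
                    fd_per_h = NA_real_, n_ref = n_ref,
                    n_detected_ref = NA_integer_, n_false = NA_integer_,
                    hours = hours)
  for (i in seq_along(thresholds)) {
    fused <- fuse_channels(threshold_decisions(smoothed, thresholds[i]))
    fused <- apply_collar(fused, collar_s, hop_s)
    det <- decisions_to_events(fused, hop_s, epoch_len_s, hours)
    g <- if (n_ref > 0) gdr(reference, det) else NA_real_
    out$gdr_pct[i] <- g
    out$n_detected_ref[i] <- if (n_ref > 0) round(g / 100 * n_ref) else 0L
    fd <- fd_per_hour(det, reference, hours)
    out$fd_per_h[i] <- fd
    out$n_false[i] <- round(fd * hours)
  }
  out
}

#' Operating point of a performance curve at a false-detection budget
#'
#' Among curve points with `fd_per_h <= target_fd_per_h`, returns the one
#' with the highest GDR (ties broken toward the lowest FD/h). If no point
#' satisfies the budget, the point with the smallest FD/h is returned with a
#' warning.
#'
#' @param curve data.frame from [performance_curve()].
#' @param target_fd_per_h false-detection budget in events/hour.
#' @return single-row data.frame (threshold, gdr_pct, fd_per_h).
#' @export
operating_point <- function(curve, target_fd_per_h) {
  if (nrow(curve) == 0) stop("empty curve")
  ok <- which(curve$fd_per_h <= target_fd_per_h)
  if (!length(ok)) {
    warning("no operating point within the FD/h budget; returning min-FD point")
    return(curve[which.min(curve$fd_per_h), ])
  }
  sub <- curve[ok, ]
  sub <- sub[order(-sub$gdr_pct, sub$fd_per_h), ]
  sub[1, ]
}

#' Detection rate by seizure duration
#'
#' Groups reference seizures into duration bins (default < 1, 1-2, 2-5 and
#' > 5 minutes) and reports the percentage detected in each bin together with
#' the bin counts. Empty bins are reported as `NA`, not 0.
#'
#' @param reference [event_list()] of labelled seizures.
#' @param detected [event_list()] of detector events.
#' @param bin_edges_min ascending interior bin edges in minutes
#'   (default `c(1, 2, 5)`).
#' @return data.frame with `bin`, `n`, `detected_pct`.
#' @export
missed_by_duration <- function(reference, detected, bin_edges_min = c(1, 2, 5)) {
  if (is.unsorted(bin_edges_min, strictly = TRUE))
    stop("bin edges must be strictly ascending")
  dur_min <- (reference$events$end_s - reference$events$start_s) / 60
  bins <- findInterval(dur_min, bin_edges_min)
  edges <- c(0, bin_edges_min, Inf)
  labs <- paste0(ifelse(is.finite(edges[-length(edges)]),
                        edges[-length(edges)], ""), "-",
                 ifelse(is.finite(edges[-1]), edges[-1], "Inf"), " min")
  hit <- vapply(seq_len(nrow(reference$events)), function(i)
    overlaps_any(reference$events$start_s[i], reference$events$end_s[i],
                 detected$events$start_s, detected$events$end_s), TRUE)
  out <- data.frame(bin = labs, n = 0L, detected_pct = NA_real_)
  for (b in seq_along(labs)) {
    in_bin <- bins == b - 1
    out$n[b] <- sum(in_bin)
    if (out$n[b] > 0) out$detected_pct[b] <- 100 * mean(hit[in_bin])
  }
  out
}

#' Summarize a dataset of per-patient recordings and seizure events
#'
#' @param record_hours numeric vector of per-patient record durations (h).
#' @param seizure_counts integer vector of per-patient seizure counts.
#' @param mean_seizure_min per-patient mean seizure durations in minutes.
#' @return list with `total_hours`, `total_seizures`, `mean_record_h` and
#'   `mean_seizure_min` (event-count-weighted mean, minutes).
#' @export
summarize_dataset <- function(record_hours, seizure_counts, mean_seizure_min) {
  if (!length(record_hours)) stop("need at least one patient")
  stopifnot(length(record_hours) == length(seizure_counts),
            length(record_hours) == length(mean_seizure_min))
  total_sz <- sum(seizure_counts)
  list(total_hours = sum(record_hours),
       total_seizures = total_sz,
       mean_record_h = sum(record_hours) / length(record_hours),
       mean_seizure_min = if (total_sz > 0)
         sum(seizure_counts * mean_seizure_min) / total_sz else NA_real_)
}

#' Reference clinical corpus summary table
#'
#' Per-patient record lengths, seizure counts and seizure-duration summaries
#' of the published 17-patient neonatal HIE EEG corpus against which the
#' detector's evaluation conventions are defined. Shipped as a plain-text
#' table under `inst/extdata`.
#'
#' @return data.frame with columns `patient`, `record_h`, `n_seizures`,
#'   `mean_seizure_s`, `min_seizure_s`, `max_seizure_s`.
#' @export
reference_corpus <- function() {
  path <- system.file("extdata", "reference_corpus.csv", package = "neoseize",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
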