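#' Default neonatal bipolar montage
#'
#' The eight bipolar derivations of the neonatal 10-20 electrode placement
#' used throughout the package: F4-C4, C4-O2, F3-C3, C3-O1, T4-C4, C4-Cz,
#' Cz-C3, C3-T3.
#'
#' @export
neonatal_montage <- function() {
  c("F4-C4", "C4-O2", "F3-C3", "C3-O1", "T4-C4", "C4-Cz", "Cz-C3", "C3-T3")
}

#' Canonicalize bipolar channel labels
#'
#' Bipolar derivation labels appear in files with hyphens, en-dashes or minus
#' signs as the electrode separator; this maps them all to a plain hyphen and
#' trims whitespace so labels compare equal.
#'
#' @param labels character vector of channel labels.
#' @return character vector of canonical labels.
#' @export
canonical_channel <- function(labels) {
  out <- gsub("[–—−]", "-", labels)
  out <- gsub("\\s*-\\s*", "-", out)
  trimws(out)
}

#' Construct a multichannel EEG recording
#'
#' An `eeg_recording` holds a multichannel EEG signal in microvolts together
#' with its sampling rate, ordered channel labels and patient identifier.
#' Samples are stored as a numeric matrix with one column per channel.
#'
#' @param samples numeric matrix, rows = time samples, columns = channels
#'   (a vector is treated as a single channel). Amplitudes in microvolts.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channels character vector of unique channel labels, one per column.
#' @param patient_id patient identifier string.
#' @param start_time offset of the first sample in seconds (default 0).
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, channels = NULL, patient_id = "unknown",
                          start_time = 0) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  if (is.null(channels)) {
    channels <- colnames(samples)
    if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(samples)))
  }
  channels <- canonical_channel(channels)
  if (length(channels) != ncol(samples))
    stop("number of channel labels must equal the number of signal columns")
  if (anyDuplicated(channels))
    stop("channel labels must be unique")
  colnames(samples) <- channels
  structure(
    list(samples = samples, fs = fs, channels = channels,
         patient_id = as.character(patient_id), start_time = start_time),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> patient %s: %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              x$patient_id, ncol(x$samples), nrow(x$samples), x$fs,
              nrow(x$samples) / x$fs))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording an `eeg_recording`.
#' @export
recording_duration <- function(recording) {
  nrow(recording$samples) / recording$fs
}

#' Construct a set of seizure annotations
#'
#' Reference seizure events for one patient. Every event is a half-open
#' interval `[start_s, end_s)` in seconds from the start of the recording,
#' optionally restricted to a subset of channels (`NA` channels = event is
#' present on all channels). Events may overlap only if they concern
#' different channels.
#'
#' @param events data.frame with columns `start_s`, `end_s` and optionally
#'   `channels` (character, `;`-separated channel sublist, `NA` or `""` for
#'   all channels).
#' @param patient_id patient identifier.
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(events, patient_id = "unknown") {
  if (is.null(events) || nrow(events) == 0) {
    events <- data.frame(start_s = numeric(0), end_s = numeric(0),
                         channels = character(0), stringsAsFactors = FALSE)
  }
  if (!all(c("start_s", "end_s") %in% names(events)))
    stop("`events` must have columns start_s and end_s")
  if (is.null(events$channels)) events$channels <- NA_character_
  events$channels <- ifelse(is.na(events$channels) | events$channels == "",
                            NA_character_, canonical_channel(events$channels))
  bad <- which(!(events$end_s > events$start_s) | events$start_s < 0)
  if (length(bad))
    stop(sprintf("invalid event at row %d: need end_s > start_s >= 0", bad[1]))
  all_ch <- is.na(events$channels)
  if (sum(all_ch) > 1) {
    ev <- events[all_ch, ]
    ev <- ev[order(ev$start_s), ]
    if (any(ev$start_s[-1] < ev$end_s[-nrow(ev)]))
      stop("all-channel events may not overlap each other")
  }
  events <- events[order(events$start_s), c("start_s", "end_s", "channels")]
  rownames(events) <- NULL
  structure(list(events = events, patient_id = as.character(patient_id)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> patient %s: %d event(s), %.1f s total\n",
              x$patient_id, nrow(x$events),
              sum(x$events$end_s - x$events$start_s)))
  invisible(x)
}

#' Channels an annotation event applies to
#'
#' @param event_channels the `channels` field of one event row.
#' @param all_channels the recording's channel labels.
#' @return character vector of channel labels.
#' @keywords internal
event_channels <- function(event_channels, all_channels) {
  if (is.na(event_channels) || event_channels == "") return(all_channels)
  intersect(strsplit(event_channels, ";", fixed = TRUE)[[1]], all_channels)
}

#' Read seizure annotations from a delimited text file
#'
#' The file is comma-separated with a header and columns
#' `patient,start_s,end_s,channels`; `channels` is an optional
#' semicolon-separated channel sublist (empty = event on all channels).
#'
#' @param path path to the CSV file.
#' @return named list of `annotation_set` objects, one per patient.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(patient = "character"))
  need <- c("patient", "start_s", "end_s")
  if (!all(need %in% names(tab)))
    stop("annotation file must have header columns patient,start_s,end_s[,channels]")
  if (is.null(tab$channels)) tab$channels <- NA_character_
  bad <- which(!is.finite(tab$start_s) | !is.finite(tab$end_s) |
                 tab$end_s <= tab$start_s | tab$start_s < 0)
  if (length(bad))
    stop(sprintf("invalid annotation at data row %d: need end_s > start_s >= 0",
                 bad[1]))
  out <- lapply(split(tab, tab$patient), function(g)
    annotation_set(g[, c("start_s", "end_s", "channels")], g$patient[1]))
  out[unique(tab$patient)]
}

#' Write annotation sets to CSV
#'
#' @param annotations a single `annotation_set` or a list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  if (inherits(annotations, "annotation_set")) annotations <- list(annotations)
  rows <- do.call(rbind, lapply(annotations, function(a) {
    if (nrow(a$events) == 0) return(NULL)
    data.frame(patient = a$patient_id, start_s = a$events$start_s,
               end_s = a$events$end_s,
               channels = ifelse(is.na(a$events$channels), "", a$events$channels),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(patient = character(0), start_s = numeric(0),
                       end_s = numeric(0), channels = character(0))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an event list
#'
#' A sorted list of non-overlapping half-open intervals `[start_s, end_s)`
#' obtained by merging overlapping inputs, together with the duration in
#' hours of the underlying record. Used by the event-based metrics.
#'
#' @param start_s,end_s numeric vectors of interval bounds in seconds.
#' @param total_duration_h duration of the underlying record in hours.
#' @return object of class `event_list` with a data.frame `events`.
#' @export
event_list <- function(start_s, end_s, total_duration_h) {
  if (length(start_s) != length(end_s)) stop("start_s and end_s lengths differ")
  if (any(end_s <= start_s)) stop("need end_s > start_s for every event")
  if (any(start_s < 0)) stop("events must start at or after 0 s")
  o <- order(start_s)
  start_s <- start_s[o]; end_s <- end_s[o]
  ms <- numeric(0); me <- numeric(0)
  for (i in seq_along(start_s)) {
    if (length(ms) && start_s[i] <= me[length(me)]) {
      me[length(me)] <- max(me[length(me)], end_s[i])
    } else {
      ms <- c(ms, start_s[i]); me <- c(me, end_s[i])
    }
  }
  structure(list(events = data.frame(start_s = ms, end_s = me),
                 total_duration_h = total_duration_h),
            class = "event_list")
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("<event_list> %d event(s) over %.2f h\n",
              nrow(x$events), x$total_duration_h))
  invisible(x)
}
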