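# Shared fixtures: all test data is generated in code at run time.

# well-separated 2-d Gaussian blobs as a training_set
make_blobs <- function(n_per_class = 100, sep = 4, sd = 1, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per_class, sep / 2, sd), ncol = 2),
             matrix(rnorm(2 * n_per_class, -sep / 2, sd), ncol = 2))
  structure(list(features = x,
                 labels = c(rep(1L, n_per_class), rep(-1L, n_per_class))),
            class = "training_set")
}

# small synthetic multichannel dataset at 64 Hz (fast path: notch skipped,
# downsampling factor 2)
tiny_dataset <- function(n_patients = 3, duration_s = 240, seed = 5) {
  generate_dataset(sim_config(
    n_patients = n_patients, duration_s = duration_s, fs = 64,
    channels = neonatal_montage()[1:4],
    seizure_rate_per_h = 30, seizure_duration_s = c(40, 80),
    seizure_channel_count = c(2, 3),
    artifact_rates = c(disconnect = 0, respiration = 0, movement = 0),
    seed = seed))
}

fast_config <- function(...) {
  detector_config(n_nonseizure = 300, C_grid = 2^4, gamma_grid = 2^-4,
                  folds = 3, ...)
}

# random event list over `hours` hours
random_events <- function(n, hours, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0)
    return(structure(list(events = data.frame(start_s = numeric(0),
                                              end_s = numeric(0)),
                          total_duration_h = hours), class = "event_list"))
  s <- sort(runif(n, 0, hours * 3600 - 120))
  event_list(s, s + runif(n, 10, 300), hours)
}

# O(n*m) brute-force interval-overlap oracles for the event metrics
brute_gdr <- function(reference, detected) {
  nr <- nrow(reference$events)
  if (nr == 0) return(NA_real_)
  hits <- 0
  for (i in seq_len(nr)) {
    hit <- FALSE
    for (j in seq_len(nrow(detected$events))) {
      lo <- max(reference$events$start_s[i], detected$events$start_s[j])
      hi <- min(reference$events$end_s[i], detected$events$end_s[j])
      if (hi > lo) hit <- TRUE
    }
    hits <- hits + hit
  }
  100 * hits / nr
}

brute_fd <- function(detected, reference, hours) {
  nf <- 0
  for (j in seq_len(nrow(detected$events))) {
    overlap <- FALSE
    for (i in seq_len(nrow(reference$events))) {
      lo <- max(reference$events$start_s[i], detected$events$start_s[j])
      hi <- min(reference$events$end_s[i], detected$events$end_s[j])
      if (hi > lo) overlap <- TRUE
    }
    nf <- nf + !overlap
  }
  nf / hours
}

# truncated-window renormalized moving-average oracle
brute_maf <- function(x, order) {
  half <- (order - 1) / 2
  sapply(seq_along(x), function(i)
    mean(x[max(1, i - half):min(length(x), i + half)]))
}
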