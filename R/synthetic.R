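# Synthetic multichannel neonatal-EEG-like data: 1/f background, rhythmic
# seizure runs confined to a channel subset, and the three artifact classes
# that dominate clinical false detections (electrode disconnect, respiration,
# movement). Ground truth is returned for every injected event so the whole
# detection chain can be exercised and scored without clinical data.

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + 97 * as.numeric(k)) %% 2147483629)
}

#' Simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: 6 patients,
#' 20 min of 8-channel 256 Hz EEG each, 1/f background with 20 uV RMS,
#' seizures at 9 events/h lasting 60-180 s with dominant frequency 1-4 Hz
#' (within the 0.5-6 Hz band where neonatal seizure frequencies concentrate)
#' and 50-150 uV amplitude on 2-4 channels, plus roughly one artifact of each
#' class per hour.
#'
#' @param n_patients number of simulated patients.
#' @param duration_s record duration per patient in seconds.
#' @param fs sampling rate in Hz.
#' @param channels channel labels.
#' @param background_amplitude_uv background RMS per channel in uV.
#' @param spectral_slope exponent alpha of the 1/f^alpha background PSD.
#' @param seizure_rate_per_h mean seizure events per hour.
#' @param seizure_duration_s range (min, max) of seizure durations in s.
#' @param seizure_dominant_hz range of the seizure dominant frequency in Hz
#'   (must lie within 0.5-13 Hz).
#' @param seizure_amplitude_uv range of seizure peak amplitudes in uV.
#' @param seizure_channel_count range of the number of channels a seizure
#'   involves.
#' @param artifact_rates named vector of per-hour rates for `disconnect`,
#'   `respiration` and `movement` artifacts.
#' @param seed global integer seed; per-record seeds are derived from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 6, duration_s = 1200, fs = 256,
                       channels = neonatal_montage(),
                       background_amplitude_uv = 20, spectral_slope = 1,
                       seizure_rate_per_h = 9,
                       seizure_duration_s = c(60, 180),
                       seizure_dominant_hz = c(1, 4),
                       seizure_amplitude_uv = c(50, 150),
                       seizure_channel_count = c(2, 4),
                       artifact_rates = c(disconnect = 1, respiration = 1,
                                          movement = 1),
                       seed = 1) {
  if (any(seizure_dominant_hz < 0.5) || any(seizure_dominant_hz > 13))
    stop("seizure_dominant_hz must lie within [0.5, 13]")
  if (any(c(seizure_rate_per_h, artifact_rates) < 0))
    stop("rates must be >= 0")
  if (any(c(duration_s, seizure_duration_s) <= 0))
    stop("durations must be positive")
  structure(as.list(environment()), class = "sim_config")
}

#' Generate 1/f-like multichannel background EEG
#'
#' Zero-mean coloured Gaussian noise per channel with power spectral density
#' proportional to `1/f^slope` across the analysis band (the shaping is
#' flattened below 0.5 Hz to keep the variance finite), normalized to the
#' requested RMS exactly.
#'
#' @param duration_s record duration in seconds.
#' @param fs sampling rate in Hz; must exceed 32 Hz (twice the 16 Hz band).
#' @param channels channel labels.
#' @param amplitude_uv per-channel RMS in uV.
#' @param slope PSD exponent (0 = white).
#' @param seed RNG seed.
#' @param patient_id patient id of the returned recording.
#' @return an [eeg_recording()].
#' @export
generate_background <- function(duration_s, fs = 256,
                                channels = neonatal_montage(),
                                amplitude_uv = 20, slope = 1, seed = 1,
                                patient_id = "sim") {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (fs <= 2 * 16) stop("fs must exceed 32 Hz (twice the 16 Hz band)")
  set.seed(seed)
  n <- round(duration_s * fs)
  freqs <- c(0, seq_len(n - 1)) * fs / n
  freqs <- pmin(freqs, fs - freqs)              # two-sided frequency axis
  shaping <- pmax(freqs, 0.5)^(-slope / 2)
  shaping[1] <- 0                               # no DC
  mat <- matrix(0, n, length(channels))
  for (j in seq_along(channels)) {
    w <- stats::rnorm(n)
    x <- Re(stats::fft(stats::fft(w) * shaping, inverse = TRUE)) / n
    x <- x - mean(x)
    mat[, j] <- x * amplitude_uv / sqrt(mean(x^2))
  }
  eeg_recording(mat, fs, channels, patient_id)
}

# raised-cosine pulse train with cycle-period jitter and sinusoidal
# amplitude modulation; peak amplitude = amplitude_uv
seizure_waveform <- function(n, fs, dominant_hz, amplitude_uv,
                             jitter = 0.2, pulse_frac = 0.65) {
  t_total <- n / fs
  starts <- c(); periods <- c()
  t <- 0
  while (t < t_total) {
    p <- (1 / dominant_hz) * (1 + stats::runif(1, -jitter, jitter))
    starts <- c(starts, t); periods <- c(periods, p)
    t <- t + p
  }
  w <- numeric(n)
  tt <- (seq_len(n) - 1) / fs
  for (i in seq_along(starts)) {
    width <- pulse_frac * periods[i]
    i0 <- max(1L, ceiling(starts[i] * fs) + 1L)
    i1 <- min(n, floor((starts[i] + width) * fs) + 1L)
    if (i1 < i0) next
    u <- (tt[i0:i1] - starts[i]) / width
    w[i0:i1] <- w[i0:i1] + 0.5 * (1 - cos(2 * pi * u))
  }
  w <- w - mean(w)
  mod_period <- max(10, t_total / 3)
  w <- w * (1 + 0.3 * sin(2 * pi * tt / mod_period))
  taper_n <- min(n %/% 4, round(2 * fs))
  if (taper_n > 1) {
    ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = taper_n)))
    w[seq_len(taper_n)] <- w[seq_len(taper_n)] * ramp
    w[n + 1 - seq_len(taper_n)] <- w[n + 1 - seq_len(taper_n)] * rev(ramp)
  }
  w * amplitude_uv / max(abs(w))
}

#' Inject a rhythmic seizure run into a recording
#'
#' Adds a sharp-wave train (raised-cosine pulse train at the dominant
#' frequency with 20% cycle-to-cycle jitter and slow sinusoidal amplitude
#' modulation) to the listed channels only, and returns the ground-truth
#' event.
#'
#' @param recording an [eeg_recording()].
#' @param start_s event onset in seconds.
#' @param duration_s event duration in seconds.
#' @param channels channels carrying the seizure (subset of the recording's).
#' @param dominant_hz dominant frequency in Hz, inside `(0, fs/2)`.
#' @param amplitude_uv peak amplitude of the discharge in uV.
#' @param seed RNG seed for the jitter.
#' @return list with the modified `recording` and the ground-truth `event`
#'   (data.frame `start_s`, `end_s`, `channels`).
#' @export
inject_seizure <- function(recording, start_s, duration_s, channels,
                           dominant_hz, amplitude_uv, seed = 1) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (dominant_hz <= 0 || dominant_hz >= recording$fs / 2)
    stop("dominant_hz must lie in (0, fs/2)")
  if (!all(channels %in% recording$channels))
    stop("seizure channels must be a subset of the recording channels")
  n_rec <- nrow(recording$samples)
  i0 <- round(start_s * recording$fs) + 1L
  i1 <- round((start_s + duration_s) * recording$fs)
  if (i0 < 1 || i1 > n_rec) stop("seizure event extends beyond the record")
  set.seed(seed)
  w <- seizure_waveform(i1 - i0 + 1L, recording$fs, dominant_hz, amplitude_uv)
  for (ch in channels)
    recording$samples[i0:i1, ch] <- recording$samples[i0:i1, ch] + w
  list(recording = recording,
       event = data.frame(start_s = start_s, end_s = start_s + duration_s,
                          channels = paste(channels, collapse = ";")))
}

#' Inject an artifact into a recording
#'
#' Three artifact classes are emulated: `disconnect` (high-amplitude
#' low-frequency drift with a residual mains-band ripple), `respiration`
#' (quasi-sinusoid at 0.3-1 Hz) and `movement` (broadband high-amplitude
#' burst). Only the listed channels are modified.
#'
#' @param recording an [eeg_recording()].
#' @param kind one of `"disconnect"`, `"respiration"`, `"movement"`.
#' @param start_s,duration_s artifact placement in seconds.
#' @param channels affected channels.
#' @param seed RNG seed.
#' @param amplitude_uv artifact amplitude scale in uV (class-specific
#'   default).
#' @return the modified [eeg_recording()].
#' @export
inject_artifact <- function(recording, kind, start_s, duration_s, channels,
                            seed = 1, amplitude_uv = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (!all(channels %in% recording$channels))
    stop("artifact channels must be a subset of the recording channels")
  fs <- recording$fs
  i0 <- round(start_s * fs) + 1L
  i1 <- round((start_s + duration_s) * fs)
  if (i0 < 1 || i1 > nrow(recording$samples))
    stop("artifact extends beyond the record")
  n <- i1 - i0 + 1L
  set.seed(seed)
  tt <- (seq_len(n) - 1) / fs
  w <- switch(kind,
    disconnect = {
      amp <- if (is.null(amplitude_uv)) 200 else amplitude_uv
      drift <- stats::filter(stats::rnorm(n), rep(1 / fs, fs), sides = 2,
                             circular = TRUE)
      drift <- as.numeric(drift) - mean(as.numeric(drift))
      drift <- drift * amp / max(abs(drift), 1e-12)
      ripple <- 10 * sin(2 * pi * min(50, fs / 2.5) * tt)
      drift + ripple
    },
    respiration = {
      amp <- if (is.null(amplitude_uv)) 60 else amplitude_uv
      f0 <- stats::runif(1, 0.3, 1)
      phase <- 2 * pi * f0 * tt + 0.3 * sin(2 * pi * 0.05 * tt)
      amp * sin(phase)
    },
    movement = {
      amp <- if (is.null(amplitude_uv)) 120 else amplitude_uv
      amp * stats::rnorm(n) / sqrt(1)
    },
    stop("unknown artifact kind: ", kind)
  )
  taper_n <- min(n %/% 4, round(1 * fs))
  if (taper_n > 1) {
    ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = taper_n)))
    w[seq_len(taper_n)] <- w[seq_len(taper_n)] * ramp
    w[n + 1 - seq_len(taper_n)] <- w[n + 1 - seq_len(taper_n)] * rev(ramp)
  }
  for (ch in channels)
    recording$samples[i0:i1, ch] <- recording$samples[i0:i1, ch] + w
  recording
}

#' Sample non-overlapping seizure events for one record
#'
#' Event count drawn from a Poisson law at `rate_per_h`, durations uniform in
#' `duration_range_s`, onsets uniform with rejection so events (plus a guard
#' gap) do not overlap. Events that cannot be placed after many tries are
#' dropped.
#'
#' @param duration_s record duration in seconds.
#' @param rate_per_h mean events per hour.
#' @param duration_range_s (min, max) event duration in seconds.
#' @param min_gap_s guard gap between events in seconds (default 30).
#' @param seed RNG seed.
#' @return data.frame with `start_s`, `end_s`, sorted by onset.
#' @export
sample_seizure_events <- function(duration_s, rate_per_h, duration_range_s,
                                  min_gap_s = 30, seed = 1) {
  expected_burden <- rate_per_h * duration_s / 3600 * mean(duration_range_s)
  if (expected_burden > 0.5 * duration_s)
    stop("infeasible packing: expected seizure time exceeds half the record")
  set.seed(seed)
  n <- stats::rpois(1, rate_per_h * duration_s / 3600)
  starts <- ends <- numeric(0)
  for (i in seq_len(n)) {
    d <- stats::runif(1, duration_range_s[1], duration_range_s[2])
    if (d + 2 * min_gap_s >= duration_s) next
    for (try in seq_len(500)) {
      s <- stats::runif(1, min_gap_s, duration_s - d - min_gap_s)
      if (!length(starts) ||
          all(s + d + min_gap_s <= starts | s >= ends + min_gap_s)) {
        starts <- c(starts, s); ends <- c(ends, s + d)
        break
      }
    }
  }
  o <- order(starts)
  data.frame(start_s = starts[o], end_s = ends[o])
}

#' Generate a full synthetic dataset with ground truth
#'
#' One record per patient: 1/f background, Poisson-placed non-overlapping
#' seizures on a random channel subset (the ground-truth annotations carry
#' the per-channel information needed for training), and artifacts of each
#' class placed in seizure-free spans and logged in a separate track.
#'
#' @param config a [sim_config()].
#' @return named list (one entry per patient) of lists with elements
#'   `recording` ([eeg_recording()]), `annotations` ([annotation_set()]) and
#'   `artifacts` (data.frame kind, start_s, end_s, channels).
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  out <- vector("list", config$n_patients)
  names(out) <- sprintf("sim%02d", seq_len(config$n_patients))
  for (k in seq_len(config$n_patients)) {
    base <- derive_seed(config$seed, k)
    pid <- names(out)[k]
    rec <- generate_background(config$duration_s, config$fs, config$channels,
                               config$background_amplitude_uv,
                               config$spectral_slope, seed = base,
                               patient_id = pid)
    events <- sample_seizure_events(config$duration_s,
                                    config$seizure_rate_per_h,
                                    config$seizure_duration_s,
                                    seed = derive_seed(base, 1))
    ev_rows <- list()
    set.seed(derive_seed(base, 2))
    for (i in seq_len(nrow(events))) {
      m <- sample(config$seizure_channel_count[1]:config$seizure_channel_count[2], 1)
      chs <- sample(config$channels, m)
      f0 <- stats::runif(1, config$seizure_dominant_hz[1],
                         config$seizure_dominant_hz[2])
      amp <- stats::runif(1, config$seizure_amplitude_uv[1],
                          config$seizure_amplitude_uv[2])
      res <- inject_seizure(rec, events$start_s[i],
                            events$end_s[i] - events$start_s[i],
                            chs, f0, amp, seed = derive_seed(base, 100 + i))
      rec <- res$recording
      ev_rows[[i]] <- res$event
    }
    ann <- annotation_set(do.call(rbind, ev_rows), pid)
    # artifacts in seizure-free spans, separate ground-truth track
    art_rows <- list()
    set.seed(derive_seed(base, 3))
    art_kinds <- names(config$artifact_rates)
    art_durations <- list(disconnect = c(30, 90), respiration = c(60, 180),
                          movement = c(10, 40))
    for (kind in art_kinds) {
      n_art <- stats::rpois(1, config$artifact_rates[[kind]] *
                              config$duration_s / 3600)
      for (i in seq_len(n_art)) {
        dr <- art_durations[[kind]]
        d <- stats::runif(1, dr[1], dr[2])
        placed <- FALSE
        for (try in seq_len(200)) {
          s <- stats::runif(1, 1, config$duration_s - d - 1)
          clear <- !nrow(ann$events) ||
            all(s + d <= ann$events$start_s | s >= ann$events$end_s)
          if (clear) { placed <- TRUE; break }
        }
        if (!placed) next
        chs <- sample(config$channels, sample(1:2, 1))
        rec <- inject_artifact(rec, kind, s, d, chs,
                               seed = derive_seed(base, 1000 + i))
        art_rows[[length(art_rows) + 1]] <-
          data.frame(kind = kind, start_s = s, end_s = s + d,
                     channels = paste(chs, collapse = ";"))
      }
    }
    arts <- if (length(art_rows)) do.call(rbind, art_rows)
      else data.frame(kind = character(0), start_s = numeric(0),
                      end_s = numeric(0), channels = character(0))
    out[[k]] <- list(recording = rec, annotations = ann, artifacts = arts)
  }
  out
}

#' Welch-averaged power spectral density
#'
#' Mean of non-overlapping segment periodograms; used to validate the
#' spectral content of generated signals.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param seg_s segment length in seconds (default 8).
#' @return list with `frequencies` and `power`.
#' @export
welch_psd <- function(x, fs, seg_s = 8) {
  seg <- round(seg_s * fs)
  n_seg <- length(x) %/% seg
  if (n_seg < 1) stop("signal shorter than one segment")
  acc <- NULL
  for (i in seq_len(n_seg)) {
    p <- periodogram(x[(i - 1) * seg + seq_len(seg)], fs)
    acc <- if (is.null(acc)) p$power else acc + p$power
  }
  list(frequencies = periodogram(x[seq_len(seg)], fs)$frequencies,
       power = acc / n_seg)
}
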