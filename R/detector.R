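#' Pipeline configuration with study defaults
#'
#' All tunable parameters of the detection chain in one list. Defaults are
#' the study operating values: 50 Hz notch, downsampling to 32 Hz with a
#' 12.8 Hz anti-aliasing cutoff, 8 s epochs with a 4 s hop, 50% epoch-label
#' overlap, 10000 sampled non-seizure training epochs, 120 s of
#' channel-annotated seizure per patient, 5-fold model selection over
#' `C = 2^(-2..12)`, `gamma = 2^(-14..2)`, moving-average order 15, 40 s
#' collar per side, decision threshold 0.5.
#'
#' @param ... named overrides of any default.
#' @return list of class `detector_config`.
#' @export
detector_config <- function(...) {
  cfg <- list(
    mains_hz = 50, target_fs = 32, cutoff_hz = 12.8,
    epoch_len_s = 8, hop_s = 4, label_overlap_frac = 0.5,
    n_nonseizure = 10000, train_seizure_s = 120,
    folds = 5, C_grid = 2^seq(-2, 12), gamma_grid = 2^seq(-14, 2),
    maf_order = 15, collar_s = 40, threshold = 0.5,
    seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "detector_config")
}

#' Fit the multichannel seizure detector
#'
#' The central fitting function. Assembles the epoch-level training set from
#' channel-annotated recordings, fits the anisotropic normalization
#' template, selects the Gaussian-kernel SVM hyperparameters by stratified
#' 5-fold cross-validation (AUC of decision values), trains the final SVM on
#' all training data, and calibrates the Platt sigmoid on out-of-fold
#' decision values from the same 5-fold split.
#'
#' @param recordings named list of [eeg_recording()] objects (per patient).
#' @param annotations named list of [annotation_set()] objects with
#'   per-channel seizure events, keyed like `recordings`.
#' @param config a [detector_config()].
#' @param feature_cache optional named list of [patient_epoch_features()]
#'   results to avoid recomputation.
#' @return object of class `seizure_detector` with components `svm`
#'   ([train_svm()] fit), `sigmoid` (Platt `A`, `B`), `normalizer`
#'   (per-feature means/SDs), `selection` (chosen `C`, `gamma`, CV table),
#'   `feature_names`, `config` and `training_info`.
#' @seealso [predict.seizure_detector()], [save_model()], [loso_evaluate()]
#' @export
fit_detector <- function(recordings, annotations, config = detector_config(),
                         feature_cache = NULL) {
  tset <- build_training_set(recordings, annotations,
                             n_nonseizure = config$n_nonseizure,
                             seed = config$seed, config = config,
                             feature_cache = feature_cache)
  normalizer <- fit_normalizer(tset$features)
  tset$features <- apply_normalizer(tset$features, normalizer)
  sel <- model_select(tset, config$C_grid, config$gamma_grid,
                      folds = config$folds, seed = config$seed)
  fit <- train_svm(tset, sel$C, sel$gamma)
  # out-of-fold decision values for unbiased sigmoid calibration
  fold <- stratified_folds(tset$labels, config$folds, config$seed)
  f_oof <- numeric(length(tset$labels))
  for (k in seq_len(config$folds)) {
    tr <- fold != k
    sub <- structure(list(features = tset$features[tr, , drop = FALSE],
                          labels = tset$labels[tr]), class = "training_set")
    mk <- train_svm(sub, sel$C, sel$gamma)
    f_oof[!tr] <- decision_values(mk, tset$features[!tr, , drop = FALSE])
  }
  sigmoid <- fit_sigmoid(f_oof, tset$labels)
  structure(
    list(svm = fit, sigmoid = sigmoid, normalizer = normalizer,
         selection = sel[c("C", "gamma", "cv_score")],
         feature_names = feature_names(), config = config,
         training_info = list(
           n_seizure = sum(tset$labels == 1),
           n_nonseizure = sum(tset$labels == -1),
           patients = unique(tset$provenance$patient),
           provenance = tset$provenance)),
    class = "seizure_detector")
}

#' @export
print.seizure_detector <- function(x, ...) {
  cat("Multichannel SVM seizure detector\n")
  cat(sprintf("  training epochs: %d seizure / %d non-seizure from %d patient(s)\n",
              x$training_info$n_seizure, x$training_info$n_nonseizure,
              length(x$training_info$patients)))
  cat(sprintf("  Gaussian kernel: C = %g, gamma = %g (CV AUC %.4f)\n",
              x$selection$C, x$selection$gamma,
              if (is.na(x$selection$cv_score)) NA else x$selection$cv_score))
  cat(sprintf("  sigmoid: A = %.4f, B = %.4f\n", x$sigmoid$A, x$sigmoid$B))
  cat(sprintf("  support vectors: %d\n", nrow(x$svm$support_vectors)))
  invisible(x)
}

#' @export
summary.seizure_detector <- function(object, ...) {
  print(object)
  cat(sprintf("  post-processing: MAF order %d, collar %g s/side, threshold %.2f\n",
              object$config$maf_order, object$config$collar_s,
              object$config$threshold))
  cat(sprintf("  features (%d): %s ...\n", length(object$feature_names),
              paste(utils::head(object$feature_names, 5), collapse = ", ")))
  invisible(object)
}

# per-epoch seizure probabilities (epochs x channels) from cached features
probability_matrix <- function(object, pf) {
  x <- apply_normalizer(pf$features, object$normalizer)
  f <- decision_values(object$svm, x)
  p <- apply_sigmoid(f, object$sigmoid)
  n_ch <- length(unique(pf$channel))
  matrix(p, ncol = n_ch,
         dimnames = list(NULL, unique(pf$channel)))
}

#' Run the detector on a recording
#'
#' Applies the full chain to a new recording: preprocessing, feature
#' extraction, normalization with the stored template, SVM decision values,
#' sigmoid probabilities, per-channel moving average, thresholding, OR
#' fusion across channels, collar, and event formation. The detector is
#' channel-count agnostic: the recording may carry any subset of (or more
#' channels than) the training montage.
#'
#' @param object a fitted `seizure_detector`.
#' @param recording an [eeg_recording()] to screen.
#' @param threshold decision threshold (default from the model config).
#' @param ... unused.
#' @return object of class `seizure_detection`: per-channel `probabilities`
#'   and `smoothed` matrices, fused `decisions`, detected `events`
#'   ([event_list()]), plus timing metadata.
#' @export
predict.seizure_detector <- function(object, recording,
                                     threshold = object$config$threshold,
                                     ...) {
  cfg <- object$config
  pf <- patient_epoch_features(recording, NULL, cfg)
  n_epochs <- dim(pf$grid$data)[2]
  hours <- recording_duration(recording) / 3600
  if (n_epochs == 0) {
    warning("recording shorter than one epoch: no decisions")
    empty <- matrix(numeric(0), 0, length(recording$channels),
                    dimnames = list(NULL, recording$channels))
    return(structure(list(probabilities = empty, smoothed = empty,
                          decisions = integer(0),
                          events = decisions_to_events(integer(0),
                                                       cfg$hop_s,
                                                       cfg$epoch_len_s, hours),
                          start_times_s = numeric(0), hop_s = cfg$hop_s,
                          epoch_len_s = cfg$epoch_len_s,
                          threshold = threshold,
                          patient_id = recording$patient_id),
                     class = "seizure_detection"))
  }
  probs <- probability_matrix(object, pf)
  smoothed <- apply(probs, 2, moving_average, order = cfg$maf_order)
  if (is.vector(smoothed)) smoothed <- matrix(smoothed, ncol = ncol(probs),
                                              dimnames = dimnames(probs))
  fused <- fuse_channels(threshold_decisions(smoothed, threshold))
  fused <- apply_collar(fused, cfg$collar_s, cfg$hop_s)
  structure(
    list(probabilities = probs, smoothed = smoothed, decisions = fused,
         events = decisions_to_events(fused, cfg$hop_s, cfg$epoch_len_s,
                                      hours),
         start_times_s = pf$grid$start_times_s, hop_s = cfg$hop_s,
         epoch_len_s = cfg$epoch_len_s, threshold = threshold,
         patient_id = recording$patient_id),
    class = "seizure_detection")
}

#' @export
print.seizure_detection <- function(x, ...) {
  cat(sprintf("<seizure_detection> patient %s: %d event(s) at threshold %.2f\n",
              x$patient_id, nrow(x$events$events), x$threshold))
  if (nrow(x$events$events))
    print(round(x$events$events, 1))
  invisible(x)
}

#' Plot a detection result
#'
#' Maximum smoothed seizure probability across channels over time, the
#' decision threshold, and the detected events.
#'
#' @param x a `seizure_detection` from [predict.seizure_detector()].
#' @param ... passed to [plot()].
#' @export
plot.seizure_detection <- function(x, ...) {
  if (!nrow(x$probabilities)) {
    warning("empty detection; nothing to plot")
    return(invisible(x))
  }
  pmax_t <- apply(x$smoothed, 1, max)
  plot(x$start_times_s, pmax_t, type = "l", ylim = c(0, 1),
       xlab = "time (s)", ylab = "max smoothed P(seizure)", ...)
  graphics::abline(h = x$threshold, lty = 2)
  if (nrow(x$events$events))
    graphics::rect(x$events$events$start_s, 0, x$events$events$end_s, 1,
                   col = grDevices::adjustcolor("red", 0.2), border = NA)
  invisible(x)
}

model_format_version <- "neoseize-model/1"

#' Save or load a fitted detector
#'
#' The model is serialized losslessly (full floating-point precision) to a
#' single JSON file: support vectors, dual coefficients, bias, kernel
#' parameters, sigmoid parameters, normalization template, feature names and
#' the configuration snapshot. Decision values of a loaded model equal those
#' of the original.
#'
#' @param model a `seizure_detector`.
#' @param path file path.
#' @return `save_model`: `path` invisibly; `load_model`: a
#'   `seizure_detector`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "seizure_detector"))
  payload <- list(
    format = model_format_version,
    support_vectors = model$svm$support_vectors,
    dual_coefs = model$svm$dual_coefs,
    rho = model$svm$rho,
    gamma = model$svm$gamma, C = model$svm$C,
    sigmoid_A = model$sigmoid$A, sigmoid_B = model$sigmoid$B,
    feature_means = unname(model$normalizer$means),
    feature_sds = unname(model$normalizer$sds),
    feature_names = model$feature_names,
    selection = model$selection,
    config = unclass(model$config),
    training_info = model$training_info[c("n_seizure", "n_nonseizure",
                                          "patients")])
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e)
                        stop("cannot parse model file: ", conditionMessage(e)))
  if (is.null(payload$format) || payload$format != model_format_version)
    stop("model file format mismatch: expected ", model_format_version,
         ", got ", payload$format %||% "<missing>")
  cfg <- payload$config
  cfg <- structure(cfg, class = "detector_config")
  norm <- list(means = stats::setNames(payload$feature_means,
                                       payload$feature_names),
               sds = stats::setNames(payload$feature_sds,
                                     payload$feature_names))
  if (any(norm$sds <= 0)) stop("invalid model file: non-positive feature SD")
  structure(
    list(svm = structure(list(support_vectors = payload$support_vectors,
                              dual_coefs = payload$dual_coefs,
                              rho = payload$rho, gamma = payload$gamma,
                              C = payload$C), class = "svm_fit"),
         sigmoid = list(A = payload$sigmoid_A, B = payload$sigmoid_B),
         normalizer = norm,
         selection = payload$selection,
         feature_names = payload$feature_names,
         config = cfg,
         training_info = payload$training_info),
    class = "seizure_detector")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
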