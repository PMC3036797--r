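# Gaussian-kernel SVM classification stage: training-set assembly,
# anisotropic normalization, 5-fold model selection, SVM training (libsvm via
# e1071) and Platt sigmoid probability calibration.

#' Assemble the epoch-level training set
#'
#' Seizure rows (+1) are epochs from channels with per-channel seizure
#' annotations, taken per patient and channel from the start of the annotated
#' seizure activity up to `train_seizure_s` seconds (default 120 s, i.e. 30
#' epochs per channel at a 4 s hop), mirroring training on a short
#' channel-annotated seizure excerpt per patient. Non-seizure rows (-1) are
#' `n_nonseizure` epochs sampled uniformly at random (fixed seed) from the
#' non-seizure spans of all channels of all patients.
#'
#' @param recordings named list of [eeg_recording()] objects (one per
#'   patient), raw (e.g. 256 Hz) or already at the analysis rate.
#' @param annotations named list of [annotation_set()] objects keyed like
#'   `recordings`.
#' @param n_nonseizure number of non-seizure epochs to sample (default 10000).
#' @param seed RNG seed for the non-seizure sample.
#' @param config pipeline configuration from [detector_config()].
#' @param feature_cache optional named list of precomputed per-patient
#'   results from [patient_epoch_features()], to avoid recomputation.
#' @return object of class `training_set`: `features` (rows x 55), `labels`
#'   (+1/-1) and a `provenance` data.frame (patient, channel, start_s).
#' @export
build_training_set <- function(recordings, annotations, n_nonseizure = 10000,
                               seed = 1, config = detector_config(),
                               feature_cache = NULL) {
  patients <- names(recordings)
  if (is.null(patients)) stop("`recordings` must be a named list")
  per <- lapply(patients, function(p) {
    if (!is.null(feature_cache) && !is.null(feature_cache[[p]]))
      feature_cache[[p]]
    else patient_epoch_features(recordings[[p]], annotations[[p]], config)
  })
  names(per) <- patients

  max_sz_per_ch <- floor(config$train_seizure_s / config$hop_s)
  sz_rows <- list(); ns_index <- list()
  for (p in patients) {
    d <- per[[p]]
    pos <- which(d$label == 1L)
    if (length(pos)) {
      keep <- unlist(lapply(split(pos, d$channel[pos]), function(idx)
        idx[order(d$start_s[idx])][seq_len(min(length(idx), max_sz_per_ch))]),
        use.names = FALSE)
      sz_rows[[p]] <- data.frame(patient = p, idx = keep)
    }
    neg <- which(d$label == -1L)
    if (length(neg)) ns_index[[p]] <- data.frame(patient = p, idx = neg)
  }
  sz <- do.call(rbind, sz_rows)
  ns <- do.call(rbind, ns_index)
  if (is.null(sz) || nrow(sz) == 0)
    stop("no seizure-annotated epochs available for training")
  if (is.null(ns)) ns <- data.frame(patient = character(0), idx = integer(0))
  set.seed(seed)
  if (nrow(ns) > n_nonseizure) {
    ns <- ns[sample.int(nrow(ns), n_nonseizure), ]
  } else if (nrow(ns) < n_nonseizure) {
    warning(sprintf("only %d non-seizure epochs available (%d requested)",
                    nrow(ns), n_nonseizure))
  }
  pick <- rbind(sz, ns)
  feats <- matrix(NA_real_, nrow(pick), 55,
                  dimnames = list(NULL, feature_names()))
  prov <- data.frame(patient = pick$patient,
                     channel = character(nrow(pick)),
                     start_s = numeric(nrow(pick)))
  for (r in seq_len(nrow(pick))) {
    d <- per[[pick$patient[r]]]
    i <- pick$idx[r]
    feats[r, ] <- d$features[i, ]
    prov$channel[r] <- d$channel[i]
    prov$start_s[r] <- d$start_s[i]
  }
  labels <- c(rep(1L, nrow(sz)), rep(-1L, nrow(ns))[seq_len(nrow(pick) - nrow(sz))])
  structure(list(features = feats, labels = labels, provenance = prov),
            class = "training_set")
}

#' Per-patient preprocessing, feature extraction and labelling
#'
#' Runs the preprocessing chain (notch if the sampling rate allows,
#' anti-aliased downsampling, epoch segmentation), extracts the 55 features
#' for every epoch and channel, and labels each epoch from the per-channel
#' annotations.
#'
#' @param recording an [eeg_recording()].
#' @param annotations an [annotation_set()] or `NULL`.
#' @param config pipeline configuration from [detector_config()].
#' @return list with `features`, `channel`, `start_s`, `label`, `grid`.
#' @export
patient_epoch_features <- function(recording, annotations = NULL,
                                   config = detector_config()) {
  rec <- recording
  if (rec$fs > 2 * config$mains_hz)
    rec <- notch_filter(rec, config$mains_hz)
  if (rec$fs != config$target_fs)
    rec <- downsample_eeg(rec, config$target_fs, config$cutoff_hz)
  grid <- segment_epochs(rec, config$epoch_len_s, config$hop_s)
  gf <- extract_grid_features(grid)
  lab <- label_epochs(grid, annotations, config$label_overlap_frac)
  # align labels (epoch x channel matrix) to the row order of the features
  lab_vec <- integer(length(gf$channel))
  for (r in seq_along(gf$channel)) {
    e <- match(gf$start_s[r], grid$start_times_s)
    lab_vec[r] <- lab[e, gf$channel[r]]
  }
  list(features = gf$features, channel = gf$channel, start_s = gf$start_s,
       label = lab_vec, grid = grid)
}

#' Fit and apply the anisotropic normalization template
#'
#' `fit_normalizer()` computes per-feature means and standard deviations on
#' the training matrix; `apply_normalizer()` centres and scales any feature
#' matrix with that template (the template fitted on training data is reused
#' unchanged on test data). A zero-variance column gets SD 1 with a warning
#' so constant features pass through centred but unscaled.
#'
#' @param features numeric matrix, one row per epoch.
#' @return `fit_normalizer`: list with `means` and `sds`.
#' @export
fit_normalizer <- function(features) {
  if (nrow(features) < 2) stop("need at least 2 rows to fit a normalizer")
  means <- colMeans(features)
  sds <- apply(features, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance feature column(s); SD set to 1",
                    sum(sds == 0)))
    sds[sds == 0] <- 1
  }
  list(means = means, sds = sds)
}

#' @rdname fit_normalizer
#' @param normalizer template from `fit_normalizer()`.
#' @export
apply_normalizer <- function(features, normalizer) {
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  sweep(sweep(features, 2, normalizer$means, "-"), 2, normalizer$sds, "/")
}

# rank-based AUC of decision scores (Wilcoxon statistic)
rank_auc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Select SVM hyperparameters by stratified cross-validation
#'
#' Grid search over `(C, gamma)` scored by the mean out-of-fold area under
#' the ROC curve of the SVM decision values, with stratified folds (default
#' 5). Deterministic for a fixed seed; ties keep the first grid point in
#' (gamma, C) order.
#'
#' @param training_set a `training_set` with normalized features.
#' @param C_grid,gamma_grid candidate values (defaults `2^seq(-2, 12, 2)` and
#'   `2^seq(-14, 2, 2)`).
#' @param folds number of CV folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @return list with `C`, `gamma`, `cv_score` and the full score `table`.
#' @export
model_select <- function(training_set, C_grid = 2^seq(-2, 12, 2),
                         gamma_grid = 2^seq(-14, 2, 2), folds = 5, seed = 1) {
  x <- training_set$features
  y <- training_set$labels
  if (length(unique(y)) < 2) stop("both classes required for model selection")
  grid <- expand.grid(C = C_grid, gamma = gamma_grid)
  if (nrow(grid) == 1)
    return(list(C = grid$C[1], gamma = grid$gamma[1], cv_score = NA_real_,
                table = grid))
  fold <- stratified_folds(y, folds, seed)
  grid$score <- NA_real_
  for (g in seq_len(nrow(grid))) {
    aucs <- numeric(folds)
    for (k in seq_len(folds)) {
      tr <- fold != k
      m <- e1071::svm(x[tr, , drop = FALSE],
                      factor(y[tr], levels = c(1, -1)),
                      kernel = "radial", gamma = grid$gamma[g],
                      cost = grid$C[g], scale = FALSE)
      f <- drop(attr(stats::predict(m, x[!tr, , drop = FALSE],
                                    decision.values = TRUE),
                     "decision.values"))
      aucs[k] <- rank_auc(f, y[!tr])
    }
    grid$score[g] <- mean(aucs, na.rm = TRUE)
  }
  best <- which.max(grid$score)
  list(C = grid$C[best], gamma = grid$gamma[best],
       cv_score = grid$score[best], table = grid)
}

#' Train the Gaussian-kernel SVM
#'
#' Soft-margin SVM with kernel `exp(-gamma * ||u - v||^2)` trained on the
#' (already normalized) training set. The returned model stores the support
#' vectors, dual coefficients and bias so the decision value
#' `f = sum_i coef_i K(sv_i, x) - rho` can be evaluated directly with
#' [decision_values()]; positive `f` means seizure.
#'
#' @param training_set a `training_set` with normalized features.
#' @param C regularization parameter.
#' @param gamma Gaussian kernel width.
#' @return list of class `svm_fit` with elements `support_vectors`,
#'   `dual_coefs`, `rho`, `gamma`, `C`.
#' @export
train_svm <- function(training_set, C, gamma) {
  y <- factor(training_set$labels, levels = c(1, -1))
  if (nlevels(droplevels(y)) < 2) stop("both classes required to train")
  m <- e1071::svm(training_set$features, y, kernel = "radial",
                  gamma = gamma, cost = C, scale = FALSE)
  structure(list(support_vectors = unname(m$SV),
                 dual_coefs = drop(m$coefs), rho = m$rho,
                 gamma = gamma, C = C),
            class = "svm_fit")
}

#' SVM decision values for a feature matrix
#'
#' @param fit an `svm_fit` from [train_svm()].
#' @param features normalized feature matrix (rows = epochs).
#' @return numeric vector of decision values `f` (positive = seizure side).
#' @export
decision_values <- function(fit, features) {
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  sv <- fit$support_vectors
  d2 <- outer(rowSums(features^2), rowSums(sv^2), "+") -
    2 * features %*% t(sv)
  d2[d2 < 0] <- 0
  drop(exp(-fit$gamma * d2) %*% fit$dual_coefs) - fit$rho
}

#' Fit the Platt sigmoid mapping decision values to probabilities
#'
#' Estimates `(A, B)` of `P(seizure | f) = 1 / (1 + exp(A f + B))` by
#' regularized maximum likelihood with the standard smoothed targets
#' `(N+ + 1)/(N+ + 2)` and `1/(N- + 2)`, using Newton iterations with
#' backtracking. For a model whose decision value increases with seizure
#' likelihood the fitted `A` is negative, so the probability is increasing
#' in `f`.
#'
#' @param f numeric vector of decision values.
#' @param labels vector of +1/-1 epoch labels.
#' @param max_iter maximum Newton iterations (default 100).
#' @return list with `A` and `B`.
#' @export
fit_sigmoid <- function(f, labels, max_iter = 100) {
  if (length(unique(labels)) < 2) stop("both labels required to fit sigmoid")
  prior1 <- sum(labels == 1); prior0 <- sum(labels != 1)
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  t <- ifelse(labels == 1, hi, lo)
  a <- 0; b <- log((prior0 + 1) / (prior1 + 1))
  obj <- function(a, b) {
    z <- a * f + b
    # stable cross-entropy of P = 1/(1+exp(z)) against targets t
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  fval <- obj(a, b)
  sigma <- 1e-12
  for (it in seq_len(max_iter)) {
    z <- a * f + b
    p <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
    d1 <- t - p                                 # dF/dz per point
    d2 <- p * (1 - p)
    g1 <- sum(f * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(f * f * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      a2 <- a + step * dA; b2 <- b + step * dB
      f2 <- obj(a2, b2)
      if (f2 < fval + 1e-4 * step * gd) {
        a <- a2; b <- b2; fval <- f2; break
      }
      step <- step / 2
      if (step < 1e-10) {
        warning("sigmoid line search failed; decision values may be separable")
        return(list(A = a, B = b))
      }
    }
  }
  list(A = a, B = b)
}

#' Convert decision values to seizure probabilities
#'
#' Overflow-safe evaluation of `P = 1 / (1 + exp(A f + B))`.
#'
#' @param f decision value(s).
#' @param sigmoid list with `A` and `B` from [fit_sigmoid()].
#' @return probabilities in (0, 1).
#' @export
apply_sigmoid <- function(f, sigmoid) {
  z <- sigmoid$A * f + sigmoid$B
  ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
}
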