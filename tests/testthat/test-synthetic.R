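test_that("background generation is deterministic and hits its RMS target", {
  a <- generate_background(30, 128, c("F4-C4", "C4-O2"), 15, 1, seed = 9)
  b <- generate_background(30, 128, c("F4-C4", "C4-O2"), 15, 1, seed = 9)
  expect_identical(a$samples, b$samples)
  flat <- generate_background(30, 128, "F4-C4", amplitude_uv = 10, slope = 0,
                              seed = 1)
  rms <- sqrt(mean(flat$samples^2))
  expect_lt(abs(rms - 10) / 10, 0.1)
  expect_error(generate_background(10, fs = 32), "fs")
})

test_that("background PSD follows the requested 1/f^alpha slope", {
  bg <- generate_background(120, 256, "F4-C4", 20, slope = 2, seed = 4)
  w <- welch_psd(bg$samples[, 1], 256, seg_s = 8)
  sel <- w$frequencies >= 1 & w$frequencies <= 12
  slope <- coef(lm(log(w$power[sel]) ~ log(w$frequencies[sel])))[2]
  expect_gt(slope, -2.4)
  expect_lt(slope, -1.6)
})

test_that("injected seizures are rhythmic at the requested frequency and
           confined to the requested channels", {
  bg <- generate_background(120, 256, neonatal_montage()[1:4], 20, 1, seed = 4)
  res <- inject_seizure(bg, 20, 80, c("F4-C4", "C4-O2"), 3, 100, seed = 5)
  expect_equal(res$event$start_s, 20)
  expect_equal(res$event$end_s, 100)
  expect_identical(res$recording$samples[, "F3-C3"], bg$samples[, "F3-C3"])
  expect_identical(res$recording$samples[, "C3-O1"], bg$samples[, "C3-O1"])
  seg <- res$recording$samples[(20 * 256 + 1):(100 * 256), "F4-C4"]
  w <- welch_psd(seg, 256, 8)
  band <- w$frequencies >= 0.5 & w$frequencies <= 12
  peak <- w$frequencies[band][which.max(w$power[band])]
  expect_lt(abs(peak - 3), 0.5)
  expect_error(inject_seizure(bg, 20, 10, "F4-C4", 200, 100), "fs/2")
  expect_error(inject_seizure(bg, 115, 20, "F4-C4", 3, 100), "beyond")
})

test_that("artifact classes have their defining signatures", {
  bg <- generate_background(120, 256, neonatal_montage()[1:2], 20, 1, seed = 6)
  resp <- inject_artifact(bg, "respiration", 10, 60, "F4-C4", seed = 1)
  expect_identical(resp$samples[, "C4-O2"], bg$samples[, "C4-O2"])
  w <- welch_psd(resp$samples[(10 * 256 + 1):(70 * 256), "F4-C4"], 256, 16)
  nz <- w$frequencies > 0
  expect_lt(w$frequencies[nz][which.max(w$power[nz])], 1.5)

  mov <- inject_artifact(bg, "movement", 10, 30, "F4-C4", seed = 2)
  seg_rms <- sqrt(mean(mov$samples[(10 * 256 + 1):(40 * 256), "F4-C4"]^2))
  expect_gte(seg_rms, 3 * 20)

  dis <- inject_artifact(bg, "disconnect", 50, 40, "C4-O2", seed = 3)
  seg <- dis$samples[(50 * 256 + 1):(90 * 256), "C4-O2"]
  expect_gt(max(abs(seg)), 100)   # high-amplitude drift

  expect_error(inject_artifact(bg, "blink", 0, 10, "F4-C4"), "unknown")
})

test_that("seizure event placement follows the Poisson/duration law", {
  none <- sample_seizure_events(3600, 0, c(60, 180), seed = 1)
  expect_equal(nrow(none), 0)
  expect_error(sample_seizure_events(600, 60, c(300, 400)), "infeasible")
  # 10 independent 1 h records at 4/h, durations U(60,180):
  # total burden ~ compound Poisson, mean 40*120 = 4800 s,
  # var = 40 * E[D^2] = 40 * (120^2 + 1200), sd ~ 790 s
  burden <- sum(vapply(1:10, function(k) {
    ev <- sample_seizure_events(3600, 4, c(60, 180), seed = 1000 + k)
    sum(ev$end_s - ev$start_s)
  }, 0))
  expect_lt(abs(burden - 4800), 3 * sqrt(40 * (120^2 + 1200)))
  # placements never overlap and respect bounds
  ev <- sample_seizure_events(3600, 8, c(60, 180), seed = 77)
  expect_true(all(ev$start_s >= 0 & ev$end_s <= 3600))
  if (nrow(ev) > 1) expect_true(all(ev$start_s[-1] >= ev$end_s[-nrow(ev)]))
})

test_that("dataset generation is reproducible and annotated", {
  d1 <- tiny_dataset(2, 200, seed = 3)
  d2 <- tiny_dataset(2, 200, seed = 3)
  expect_identical(d1[[1]]$annotations$events, d2[[1]]$annotations$events)
  expect_identical(d1[[2]]$recording$samples, d2[[2]]$recording$samples)
  # per-channel ground truth present
  for (p in names(d1)) {
    ev <- d1[[p]]$annotations$events
    if (nrow(ev)) expect_true(all(nzchar(ev$channels)))
  }
  zero <- generate_dataset(sim_config(n_patients = 1, duration_s = 120,
                                      fs = 64, seizure_rate_per_h = 0,
                                      seed = 1))
  expect_equal(nrow(zero[[1]]$annotations$events), 0)
})

test_that("generated seizure epochs are linearly separable from background
           on three summary features", {
  set.seed(10)
  n_rec <- 10
  seg_s <- 208   # 50 epochs per record at a 4 s hop
  feats <- list(); labs <- integer(0)
  for (k in 1:n_rec) {
    bg <- generate_background(seg_s + 8, 64, c("F4-C4"), 20, 1, seed = 100 + k)
    f0 <- runif(1, 1, 4)
    sz <- inject_seizure(bg, 2, seg_s + 4, "F4-C4", f0,
                         runif(1, 50, 150), seed = 200 + k)$recording
    for (rec_lab in list(list(r = bg, y = 0L), list(r = sz, y = 1L))) {
      grid <- segment_epochs(downsample_eeg(rec_lab$r, 32), 8, 4)
      n_e <- min(50, dim(grid$data)[2])
      for (e in seq_len(n_e)) {
        psd <- compute_psd(grid$data[, e, 1])
        fr <- frequency_features(psd, 0)
        inf <- info_features(grid$data[, e, 1], psd)
        feats[[length(feats) + 1]] <- c(fr["total_power"], fr["peak_freq"],
                                        inf["spectral_entropy"])
        labs <- c(labs, rec_lab$y)
      }
    }
  }
  x <- do.call(rbind, feats)
  expect_gte(sum(labs == 1), 500)
  expect_gte(sum(labs == 0), 500)
  df <- data.frame(y = labs, tp = log10(x[, 1] + 1e-12), pf = x[, 2],
                   se = x[, 3])
  m <- suppressWarnings(glm(y ~ tp + pf + se, binomial, df))
  acc <- mean((fitted(m) > 0.5) == (df$y == 1))
  expect_gte(acc, 0.95)
})
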