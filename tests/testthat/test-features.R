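test_that("the PSD is a power-conserving one-sided periodogram", {
  expect_equal(compute_psd(rep(0, 256))$power, rep(0, 129))
  s4 <- sin(2 * pi * 4 * (0:255) / 32)
  psd <- compute_psd(s4)
  expect_equal(psd$frequencies[which.max(psd$power)], 4)
  expect_equal(psd$frequencies[2] - psd$frequencies[1], 0.125)
  set.seed(13)
  for (i in 1:20) {
    x <- rnorm(256, 0, runif(1, 0.1, 50))
    p <- compute_psd(x)
    expect_lt(abs(sum(p$power) - mean(x^2)) / mean(x^2), 1e-9)
  }
  expect_error(compute_psd(rnorm(100)), "256")
})

test_that("spectral edge frequencies match a cumulative-sum oracle", {
  # analytically flat PSD over 0-12 Hz: SEF90 at the 88th of 97 bins
  flat <- list(frequencies = seq(0, 16, by = 0.125),
               power = c(rep(1, 97), rep(0, 32)))
  ff <- frequency_features(flat, 0)
  expect_lt(abs(ff[["sef90"]] - 10.8), 0.126)
  brute_sef <- function(psd, frac) {
    sel <- psd$frequencies <= 12
    p <- psd$power[sel]; f <- psd$frequencies[sel]
    acc <- 0
    for (i in seq_along(p)) {
      acc <- acc + p[i]
      if (acc >= frac * sum(p)) return(f[i])
    }
    0
  }
  set.seed(14)
  for (i in 1:200) {
    psd <- list(frequencies = seq(0, 16, by = 0.125),
                power = rexp(129, 1) * runif(1, 0.01, 10))
    ff <- frequency_features(psd, 0)
    for (fr in c(0.80, 0.90, 0.95)) {
      key <- paste0("sef", fr * 100)
      expect_equal(ff[[key]], brute_sef(psd, fr))
    }
  }
})

test_that("frequency features satisfy their definitional identities", {
  s3 <- sin(2 * pi * 3 * (0:255) / 32)
  ff <- frequency_features(compute_psd(s3), wavelet_energy(s3))
  expect_equal(ff[["peak_freq"]], 3)
  set.seed(15)
  x <- rnorm(256)
  fx <- frequency_features(compute_psd(x), wavelet_energy(x))
  bp <- fx[grep("^bp_", names(fx))]
  nbp <- fx[grep("^nbp_", names(fx))]
  expect_equal(unname(nbp), unname(bp) / fx[["total_power"]])
  # zero signal: flagged zeros, no NaN
  f0 <- frequency_features(compute_psd(rep(0, 256)), 0)
  expect_true(all(is.finite(f0)))
})

test_that("wavelet energy is band-selective and energy-conserving", {
  # a 1.5 Hz tone at 32 Hz lives in the level-4 (1-2 Hz) detail band
  tone <- sin(2 * pi * 1.5 * (0:255) / 32)
  e <- vapply(1:7, function(l) wavelet_energy(tone, l), 0)
  expect_equal(which.max(e), 4)
  # orthonormal transform: band energies sum to the total energy
  set.seed(16)
  x <- rnorm(256)
  details <- sum(vapply(1:8, function(l) wavelet_energy(x, l), 0))
  expect_lt(abs(details / sum(x^2) - 1), 0.01) # approx coefficient at level 8
  expect_equal(wavelet_energy(2 * x) / wavelet_energy(x), 4)
})

test_that("time-domain features match analytic cases", {
  const <- rep(3, 256)
  tf <- time_features(const)
  expect_equal(tf[["curve_length"]], 0)
  expect_equal(tf[["rms"]], 3)
  expect_equal(tf[["zero_crossings"]], 0)
  expect_equal(tf[["var_d1"]], 0)
  expect_true(all(is.finite(tf)))
  # 2 Hz unit sinusoid over 8 s: 16 cycles x 2 = 32 sign changes
  s2 <- sin(2 * pi * 2 * (0:255) / 32 - 0.1)
  expect_equal(time_features(s2)[["zero_crossings"]], 32)
  # nested AR fits: prediction error non-increasing in order
  set.seed(17)
  for (i in 1:20) {
    tf <- time_features(rnorm(256))
    ar <- tf[grep("^ar_err_", names(tf))]
    expect_true(all(diff(ar) <= 1e-10))
    expect_true(all(ar > 0))
  }
})

test_that("information-theory features match degenerate and uniform cases", {
  const <- rep(2, 256)
  inf <- info_features(const, compute_psd(const - 2))
  expect_equal(inf[["svd_entropy"]], 0)
  # PSD concentrated in one bin
  s4 <- sin(2 * pi * 4 * (0:255) / 32)
  expect_lt(info_features(s4, compute_psd(s4))[["spectral_entropy"]], 0.02)
  # uniform amplitude histogram over 2^k bins -> k bits
  u <- rep(seq(0, 7) / 7, each = 32)
  expect_equal(shannon_entropy(u, n_bins = 8, base = 2), 3)
})

test_that("the full vector has 55 finite values and documented scaling", {
  set.seed(18)
  x <- rnorm(256, 0, 20)
  v <- extract_features(x)
  expect_length(v, 55)
  expect_identical(names(v), feature_names())
  expect_identical(extract_features(x), v)   # deterministic
  v2 <- extract_features(2 * x)
  scale_free <- c("peak_freq", "sef80", "sef90", "sef95",
                  paste0("nbp_", paste0(0:10, "_", 2:12)),
                  "zero_crossings", "zero_crossings_d1", "zero_crossings_d2",
                  "skewness", "kurtosis", "hjorth_mobility",
                  "hjorth_complexity", "shannon_entropy", "svd_entropy",
                  "spectral_entropy")
  expect_equal(v2[scale_free], v[scale_free], tolerance = 1e-9)
  quad <- c("total_power", paste0("bp_", paste0(0:10, "_", 2:12)),
            "wavelet_energy", "hjorth_activity",
            paste0("ar_err_", 1:9), "nonlinear_energy", "var_d1", "var_d2")
  expect_equal(unname(v2[quad] / v[quad]), rep(4, length(quad)),
               tolerance = 1e-9)
  lin <- c("curve_length", "rms")
  expect_equal(unname(v2[lin] / v[lin]), rep(2, length(lin)),
               tolerance = 1e-12)
})

test_that("feature extraction never produces NaN or Inf on random epochs", {
  set.seed(19)
  scales <- c(1e-4, 1, 1e4)
  for (i in 1:600) {
    x <- rnorm(256, 0, scales[1 + i %% 3])
    expect_true(all(is.finite(extract_features(x))))
  }
  # pathological epochs
  expect_true(all(is.finite(extract_features(rep(0, 256)))))
  expect_true(all(is.finite(extract_features(rep(-7.2, 256)))))
  expect_true(all(is.finite(extract_features(rep(c(-1, 1), 128)))))
})
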