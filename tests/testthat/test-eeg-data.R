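test_that("recording constructor enforces its invariants", {
  m <- matrix(rnorm(512), ncol = 2)
  expect_error(eeg_recording(m, fs = -1), "positive")
  expect_error(eeg_recording(m, 256, c("A", "A")), "unique")
  expect_error(eeg_recording(m, 256, c("A")), "labels")
  r <- eeg_recording(m, 256, c("F4–C4", "C4 - O2"))
  expect_identical(r$channels, c("F4-C4", "C4-O2"))  # en dash canonicalized
})

test_that("EDF round-trip preserves samples within one quantization step", {
  set.seed(2)
  rec <- eeg_recording(matrix(rnorm(2560 * 2, 0, 30), ncol = 2), 256,
                       c("F4-C4", "C4-O2"), "p1")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$fs, 256)
  expect_identical(back$channels, rec$channels)
  expect_identical(back$patient_id, "p1")
  expect_equal(nrow(back$samples), 2560)
  qstep <- 2 * max(abs(rec$samples)) / (2^16 - 1)
  expect_lt(max(abs(back$samples - rec$samples)), qstep)
})

test_that("referential EDF electrodes are combined into the bipolar montage", {
  set.seed(3)
  el <- eeg_recording(matrix(rnorm(1024 * 3, 0, 10), ncol = 3), 256,
                      c("F4", "C4", "O2"), "p2")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(el, path)
  back <- read_edf(path)
  # only the two derivable pairs of the eight-channel montage
  expect_identical(back$channels, c("F4-C4", "C4-O2"))
  qstep <- 4 * max(abs(el$samples)) / (2^16 - 1)
  expect_lt(max(abs(back$samples[, "F4-C4"] -
                      (el$samples[, 1] - el$samples[, 2]))), qstep)
})

test_that("EDF writer and reader reject invalid input", {
  rec <- eeg_recording(matrix(numeric(0), ncol = 1), 256, "F4-C4")
  path <- withr::local_tempfile(fileext = ".edf")
  expect_error(write_edf(rec, path), "zero-length")
  bad <- eeg_recording(matrix(c(1, NA, 3, 4), ncol = 1), 256, "F4-C4")
  expect_error(write_edf(bad, path), "non-finite")
  writeLines("this is not an EDF file", path)
  expect_error(read_edf(path), "EDF")
  expect_error(read_edf(file.path(tempdir(), "nope.edf")), "not found")
})

test_that("annotation CSV parsing validates and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient,start_s,end_s,channels",
               "p1,10,250,",
               "p1,300,360,F3–C3;Cz-C3",
               "p2,5,20,"), path)
  anns <- read_annotations(path)
  expect_named(anns, c("p1", "p2"))
  expect_equal(anns$p1$events$end_s[1] - anns$p1$events$start_s[1], 240)
  expect_true(is.na(anns$p1$events$channels[1]))
  expect_identical(event_channels(anns$p1$events$channels[2],
                                  neonatal_montage()),
                   c("F3-C3", "Cz-C3"))
  # write-read identity
  out <- withr::local_tempfile(fileext = ".csv")
  write_annotations(anns, out)
  again <- read_annotations(out)
  expect_equal(again$p1$events, anns$p1$events)
  expect_equal(again$p2$events, anns$p2$events)

  writeLines(c("patient,start_s,end_s,channels", "p1,50,40,"), path)
  expect_error(read_annotations(path), "row 1")
})

test_that("annotation constructor rejects inverted and overlapping events", {
  expect_error(annotation_set(data.frame(start_s = 5, end_s = 5)), "end_s")
  expect_error(annotation_set(data.frame(start_s = -1, end_s = 5)), "start_s")
  expect_error(
    annotation_set(data.frame(start_s = c(0, 50), end_s = c(100, 120))),
    "overlap")
  # overlap on different channels is allowed
  ok <- annotation_set(data.frame(start_s = c(0, 50), end_s = c(100, 120),
                                  channels = c("F4-C4", "C4-O2")))
  expect_equal(nrow(ok$events), 2)
})

test_that("saved models reload losslessly and reproduce decision values", {
  ts <- make_blobs(60, seed = 4)
  fit <- train_svm(ts, C = 10, gamma = 0.5)
  model <- structure(
    list(svm = fit, sigmoid = list(A = -1.7, B = 0.21),
         normalizer = list(means = stats::setNames(rep(0, 2), c("a", "b")),
                           sds = stats::setNames(rep(1, 2), c("a", "b"))),
         selection = list(C = 10, gamma = 0.5, cv_score = NA),
         feature_names = c("a", "b"), config = detector_config(),
         training_info = list(n_seizure = 60, n_nonseizure = 60,
                              patients = "p")),
    class = "seizure_detector")
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  set.seed(8)
  probe <- matrix(rnorm(200), ncol = 2)
  expect_lt(max(abs(decision_values(back$svm, probe) -
                      decision_values(model$svm, probe))), 1e-10)
  expect_equal(back$sigmoid, model$sigmoid)
  expect_equal(back$config$maf_order, model$config$maf_order)

  writeLines(substr(paste(readLines(path), collapse = ""), 1, 50), path)
  expect_error(load_model(path), "parse|format")
  jsonlite::write_json(list(format = "other/9"), path, auto_unbox = TRUE)
  expect_error(load_model(path), "format mismatch")
})
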