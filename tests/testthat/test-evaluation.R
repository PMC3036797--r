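test_that("consecutive positive decisions are joined into merged events", {
  empty <- decisions_to_events(rep(0L, 10))
  expect_equal(nrow(empty$events), 0)
  # epochs 1..5 positive (starts 0..16 s, length 8): one event [0, 24)
  d <- c(rep(1L, 5), rep(0L, 5))
  ev <- decisions_to_events(d, 4, 8)
  expect_equal(ev$events, data.frame(start_s = 0, end_s = 24))
  # 1,0,1: epoch spans [0,8) and [8,16) touch -> merged
  ev2 <- decisions_to_events(c(1L, 0L, 1L, 0L), 4, 8)
  expect_equal(nrow(ev2$events), 1)
  expect_equal(ev2$events$end_s, 16)
  expect_equal(decisions_to_events(rep(1L, 10), 4, 8)$total_duration_h,
               (9 * 4 + 8) / 3600)
})

test_that("GDR and FD/h follow the event-overlap definitions", {
  ref <- event_list(c(0, 100, 200), c(50, 150, 260), 1)
  all_hit <- event_list(0, 300, 1)
  expect_equal(gdr(ref, all_hit), 100)
  none <- decisions_to_events(rep(0L, 5))
  expect_equal(gdr(ref, none), 0)
  two <- event_list(c(10, 120), c(20, 130), 1)
  expect_equal(gdr(ref, two), 200 / 3, tolerance = 1e-9)
  empty_ref <- structure(list(events = data.frame(start_s = numeric(0),
                                                  end_s = numeric(0)),
                              total_duration_h = 1), class = "event_list")
  expect_warning(g <- gdr(empty_ref, all_hit), "undefined")
  expect_true(is.na(g))
  # 2 non-overlapping detections in half an hour -> 4 FD/h
  det <- event_list(c(500, 900), c(520, 930), 0.5)
  expect_equal(fd_per_hour(det, ref, 0.5), 4)
  expect_equal(fd_per_hour(all_hit, ref, 1), 0)
  expect_error(fd_per_hour(det, ref, 0), "positive")
  # a detection that overlaps one reference and extends past it is not an FD
  span <- event_list(40, 110, 1)
  expect_equal(fd_per_hour(span, ref, 1), 0)
  expect_equal(gdr(ref, span), 200 / 3, tolerance = 1e-9)
})

test_that("event metrics agree with the brute-force overlap oracle", {
  set.seed(30)
  for (i in 1:500) {
    hours <- runif(1, 0.5, 4)
    ref <- random_events(sample(0:8, 1), hours)
    det <- random_events(sample(0:12, 1), hours)
    if (nrow(ref$events) > 0)
      expect_equal(gdr(ref, det), brute_gdr(ref, det))
    expect_equal(fd_per_hour(det, ref, hours), brute_fd(det, ref, hours))
    expect_gte(fd_per_hour(det, ref, hours), 0)
    if (nrow(ref$events) > 0) {
      g <- gdr(ref, det)
      expect_true(g >= 0 && g <= 100)
    }
  }
})

test_that("threshold sweeps produce monotone GDR and sane endpoints", {
  set.seed(31)
  n <- 200
  probs <- matrix(runif(n * 2, 0, 0.45), n, 2)
  # one obvious seizure: high probability plateau on channel 1
  probs[80:110, 1] <- 0.97
  hours <- ((n - 1) * 4 + 8) / 3600
  ref <- event_list(80 * 4, 110 * 4, hours)
  curve <- performance_curve(probs, ref, seq(0, 1, by = 0.02))
  expect_equal(curve$gdr_pct[1], 100)              # threshold 0
  expect_equal(curve$gdr_pct[nrow(curve)], 0)      # threshold 1 > max prob
  expect_equal(curve$fd_per_h[nrow(curve)], 0)
  expect_true(any(curve$gdr_pct == 100 & curve$fd_per_h == 0))
  expect_true(all(diff(curve$gdr_pct) <= 1e-9))
  # monotone on random fixtures too
  for (i in 1:5) {
    p2 <- matrix(runif(100 * 3), 100, 3)
    r2 <- random_events(3, (99 * 4 + 8) / 3600)
    c2 <- performance_curve(p2, r2, seq(0, 1, by = 0.05))
    expect_true(all(diff(c2$gdr_pct) <= 1e-9))
  }
  expect_error(performance_curve(probs, ref, numeric(0)), "empty")
})

test_that("operating points respect the FD/h budget", {
  curve <- data.frame(threshold = c(0.5, 0.6),
                      gdr_pct = c(100, 90), fd_per_h = c(0.8, 0.4))
  expect_equal(operating_point(curve, 0.5)$threshold, 0.6)
  expect_equal(operating_point(curve, Inf)$gdr_pct, 100)
  expect_equal(operating_point(curve[1, ], Inf)$threshold, 0.5)
  expect_warning(op <- operating_point(curve, 0.1), "budget")
  expect_equal(op$fd_per_h, 0.4)
})

test_that("duration-binned detection rates are computed per bin", {
  ref <- event_list(c(0, 200, 600), c(30, 290, 960), 1)   # 30 s, 90 s, 360 s
  det <- event_list(c(210, 700), c(220, 710), 1)          # last two detected
  mb <- missed_by_duration(ref, det)
  expect_equal(mb$detected_pct, c(0, 100, NA, 100))
  expect_equal(mb$n, c(1L, 1L, 0L, 1L))
  all_det <- missed_by_duration(ref, event_list(0, 1000, 1))
  expect_true(all(all_det$detected_pct[all_det$n > 0] == 100))
  expect_error(missed_by_duration(ref, det, c(2, 1)), "ascending")
})

test_that("dataset summary arithmetic reproduces the reference corpus", {
  d <- reference_corpus()
  s <- summarize_dataset(d$record_h, d$n_seizures, d$mean_seizure_s / 60)
  expect_equal(s$total_hours, 267.9)
  expect_equal(s$total_seizures, 705)
  expect_equal(round(s$mean_record_h, 2), 15.76)
  expect_equal(round(s$mean_seizure_min, 2), 3.89)
  one <- summarize_dataset(1, 1, 1)
  expect_equal(unlist(one), c(total_hours = 1, total_seizures = 1,
                              mean_record_h = 1, mean_seizure_min = 1))
})
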