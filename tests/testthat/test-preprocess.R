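test_that("resampling scales lengths, preserves identity, and tracks a known sine", {
  rec <- waveform_record(sin(2 * pi * 1 * (0:4999) / 500), NULL, 500, "SR")
  out <- resample_record(rec, 100)
  expect_equal(out$fs, 100)
  expect_length(out$ecg, 1000)
  # against the analytically sampled sine
  ref <- sin(2 * pi * 1 * (0:999) / 100)
  expect_gt(cor(out$ecg, ref), 0.999)

  same <- resample_record(rec, 500)
  expect_identical(same$ecg, rec$ecg)

  # annotations are re-indexed proportionally
  rec2 <- waveform_record(rnorm(5000), NULL, 500, "mixed",
                          annotations = data.frame(start = c(0, 2500),
                                                   end = c(2500, 5000),
                                                   rhythm = c("AF", "SR")))
  out2 <- resample_record(rec2, 100)
  expect_equal(out2$annotations$start, c(0, 500))
  expect_equal(out2$annotations$end, c(500, 1000))
})

test_that("R-peak detection is accurate on clean signals and silent on degenerate ones", {
  rec <- clean_record("SR", mean_hr = 60, duration_s = 30, seed = 5)
  b <- detect_r_peaks(rec$ecg, 100)
  expect_gte(length(b$peak_indices), 29)
  expect_lte(length(b$peak_indices), 31)
  truth <- rec$beat_times[rec$beat_times < 30 - 0.02]
  det <- (b$peak_indices - 1) / 100
  errs <- vapply(truth, function(t) min(abs(det - t)), numeric(1))
  expect_lt(max(errs), 0.02)

  expect_length(detect_r_peaks(numeric(0), 100)$peak_indices, 0)
  expect_length(detect_r_peaks(rep(0, 5000), 100)$peak_indices, 0)
  expect_length(detect_r_peaks(rnorm(50), 100)$peak_indices, 0)
})

test_that("detected AF RR variability recovers the generating coefficient of variation", {
  rec <- clean_record("AF", mean_hr = 80, duration_s = 60, seed = 8)
  b <- detect_r_peaks(rec$ecg, 100)
  iv <- beat_intervals(b)
  cv <- sd(iv) / mean(iv)
  # oracle: the generating RR sequence inside the 60-s record
  truth <- rec$rr[cumsum(rec$rr) < 60]
  cv_true <- sd(truth) / mean(truth)
  expect_lt(abs(cv - cv_true) / cv_true, 0.2)
})

test_that("PPG peak detection matches constructed pulse times and beat counts", {
  rec <- clean_record("SR", mean_hr = 60, duration_s = 30, seed = 6)
  p <- detect_ppg_peaks(rec$ppg, 100)
  expect_gte(length(p$peak_indices), 29)
  expect_lte(length(p$peak_indices), 31)
  truth <- rec$pulse_times[rec$pulse_times < 30 - 0.03]
  det <- (p$peak_indices - 1) / 100
  errs <- vapply(truth, function(t) min(abs(det - t)), numeric(1))
  expect_lt(max(errs), 0.03)

  r <- detect_r_peaks(rec$ecg, 100)
  expect_equal(length(p$peak_indices), length(r$peak_indices))
  expect_length(detect_ppg_peaks(rep(0.5, 5000), 100)$peak_indices, 0)
})

test_that("interval correlation is 1 for shifted copies and discriminates shared vs independent rhythms", {
  a <- beat_series(c(100, 200, 320, 410, 530), 100, "ECG")
  b <- beat_series(c(100, 200, 320, 410, 530) + 25, 100, "PPG")
  expect_equal(interval_correlation(a, b), 1.0)

  rec <- clean_record("AF", seed = 14)
  expect_gt(interval_correlation(detect_r_peaks(rec$ecg, 100),
                                 detect_ppg_peaks(rec$ppg, 100)), 0.96)

  other <- clean_record("AF", seed = 15)
  expect_lt(interval_correlation(detect_r_peaks(rec$ecg, 100),
                                 detect_ppg_peaks(other$ppg, 100)), 0.96)

  short <- beat_series(c(10, 50), 100, "ECG")
  expect_true(is.na(interval_correlation(short, a)))
})

test_that("qc_screen applies the correlation threshold and heart-rate floor", {
  rec <- clean_record("AF", seed = 21)
  q <- qc_screen(rec)
  expect_true(q$passed)
  expect_gt(q$interval_correlation, 0.96)

  # an impossible threshold fails nearly everything
  q1 <- qc_screen(rec, threshold = 1.0)
  expect_false(q1$passed)
  expect_match(paste(q1$reasons, collapse = " "), "correlation")

  # 25 bpm record: excluded by the HR floor
  m <- morphology_spec(noise_sd = 0)
  rr <- rep(2.4, 15)
  slow <- waveform_record(minmax_scale(as.numeric(synth_ecg(rr, m, 100))),
                          minmax_scale(as.numeric(synth_ppg(rr, m, 100))),
                          100, "SR")
  q2 <- qc_screen(slow)
  expect_false(q2$passed)
  expect_match(paste(q2$reasons, collapse = " "), "floor")
  expect_lt(q2$mean_hr, 30)
})

test_that("segmentation emits only whole windows fully inside matching annotations", {
  fs <- 100
  rec <- waveform_record(rnorm(9500), rnorm(9500), fs, "AF",
                         annotations = data.frame(start = 0, end = 9500,
                                                  rhythm = "AF"))
  st <- segment_annotated(rec, "AF", seconds = 30)
  expect_equal(n_segments(st), 3)   # floor(95 / 30)
  expect_equal(ncol(st$segments), 3000)

  short <- waveform_record(rnorm(2900), rnorm(2900), fs, "AF")
  expect_equal(n_segments(segment_annotated(short, "AF", 30)), 0)

  # two disjoint 60-s AF spans with an SR gap: 4 windows, none crossing
  ann <- data.frame(start = c(0, 7000), end = c(6000, 13000),
                    rhythm = c("AF", "AF"))
  x <- rnorm(13000)
  rec2 <- waveform_record(x, x, fs, "AF", annotations = ann)
  st2 <- segment_annotated(rec2, "AF", 30)
  expect_equal(n_segments(st2), 4)
  # windows start at annotation-aligned offsets only
  expect_equal(st2$segments[3, 1], x[7001])

  expect_equal(n_segments(segment_annotated(rec2, "SR", 30)), 0)
})

test_that("the slicing law yields 15 slices per 30-s parent and the printed totals", {
  fs <- 100
  parent <- segment_store(matrix(rnorm(3000), 1, 3000), "AF", "real", "p1",
                          fs = fs, segment_seconds = 30)
  sl <- slice_segments(parent, 15, 1)
  expect_equal(n_segments(sl), 15)
  expect_equal(ncol(sl$segments), 1500)
  # the full sliding-window formula admits 16; compatibility mode drops one
  expect_equal(n_segments(slice_segments(parent, 15, 1, drop_last = FALSE)), 16)
  # identity window: exactly one slice regardless of mode
  expect_equal(n_segments(slice_segments(parent, 30, 1)), 1)

  # count law at scale (coarse rate keeps the matrix small; counts depend
  # only on the window arithmetic)
  many <- segment_store(matrix(0, 770, 60), rep("AF", 770), "real",
                        sprintf("p%03d", 1:770), fs = 2, segment_seconds = 30)
  expect_equal(n_segments(slice_segments(many, 15, 1)), 11550)
  expect_error(slice_segments(parent, 15, 0), "stride")
  expect_error(slice_segments(parent, 31, 1), "exceeds")
})

test_that("slices inherit labels and provenance and never cross parent boundaries", {
  seg <- matrix(rep(1:3, each = 60), 3, 60, byrow = TRUE)
  st <- segment_store(seg, c("AF", "SR", "AF"), c("real", "real", "generated"),
                      c("a", "b", "c"), fs = 2, segment_seconds = 30)
  sl <- slice_segments(st, 15, 1)
  expect_equal(n_segments(sl), 45)
  expect_equal(unique(sl$labels[sl$parent_id == "b"]), "SR")
  expect_equal(unique(sl$origin[sl$parent_id == "c"]), "generated")
  # every slice is constant at its parent's value: no boundary crossing
  expect_true(all(apply(sl$segments, 1, function(r) length(unique(r)) == 1)))
})

test_that("segment store CSV round trip preserves geometry and sidecar", {
  st <- cohort_pairs(4, seed = 31)
  prefix <- file.path(withr::local_tempdir(), "store")
  write_store(st, prefix)
  back <- read_store(prefix)
  expect_equal(back$segments, st$segments, tolerance = 1e-12)
  expect_equal(back$ecg, st$ecg, tolerance = 1e-12)
  expect_equal(back$labels, st$labels)
  expect_equal(back$parent_id, st$parent_id)
})
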