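test_that("simulated RR series have the specified mean and rhythm statistics", {
  rr_sr <- simulate_rr(rhythm_spec("SR", mean_hr = 60, seed = 3), 1000)
  expect_true(all(rr_sr > 0))
  expect_lt(abs(mean(rr_sr) - 1.0), 0.02)

  rr_af <- simulate_rr(rhythm_spec("AF", mean_hr = 60, af_cv = 0.2, seed = 3), 1000)
  expect_lt(abs(mean(rr_af) - 1.0), 0.03)
  # AF is strictly more irregular than SR at equal mean rate
  expect_gt(sd(rr_af), sd(rr_sr))
  # AF CV close to the specified coefficient of variation
  expect_lt(abs(sd(rr_af) / mean(rr_af) - 0.2), 0.04)
})

test_that("AF RR series are serially uncorrelated; SR series peak at the RSA frequency", {
  for (s in c(1, 2, 3)) {
    rr <- simulate_rr(rhythm_spec("AF", mean_hr = 75, seed = s), 1000)
    expect_lt(abs(cor(rr[-1], rr[-length(rr)])), 0.1)
  }
  # SR: interpolate RR(t) onto a uniform grid and locate the spectral peak
  spec <- rhythm_spec("SR", mean_hr = 60, seed = 9)
  rr <- simulate_rr(spec, 500)
  tt <- cumsum(rr)
  grid <- seq(tt[1], tt[length(tt)], by = 0.25)
  u <- approx(tt, rr, xout = grid)$y
  u <- u - mean(u)
  pw <- Mod(fft(u))^2
  freqs <- (seq_along(u) - 1) / (length(u) * 0.25)
  band <- freqs > 0.05 & freqs < 1
  expect_lt(abs(freqs[band][which.max(pw[band])] - spec$sr_rsa_freq), 0.05)
})

test_that("rhythm and morphology specs reject invalid parameters", {
  expect_error(rhythm_spec("SR", mean_hr = 25), "mean_hr")
  expect_error(rhythm_spec("AF", mean_hr = 250), "mean_hr")
  expect_error(simulate_rr(rhythm_spec("AF"), 0), "positive count")
  bad <- default_ecg_waves()
  bad$amp[bad$wave == "P"] <- 2
  expect_error(morphology_spec(ecg_waves = bad), "R wave")
  expect_error(morphology_spec(ptt = -0.1), "ptt")
})

test_that("synthesized waveforms have formula lengths and exact beat placement", {
  m <- morphology_spec(noise_sd = 0)
  rr <- rep(1, 10)
  ecg <- synth_ecg(rr, m, fs = 100)
  expect_length(as.numeric(ecg), 1000)
  ppg <- synth_ppg(rr, m, fs = 100)
  expect_length(as.numeric(ppg), 1000)

  # R-peak detector recovers the constructed beat times within 20 ms
  b <- detect_r_peaks(as.numeric(ecg), 100)
  expect_length(b$peak_indices, 10)
  expect_lt(max(abs((b$peak_indices - 1) / 100 - attr(ecg, "beat_times"))), 0.02)

  # systolic peak count matches the beat count
  p <- detect_ppg_peaks(as.numeric(ppg), 100)
  expect_length(p$peak_indices, length(rr))

  # noiseless synthesis is bit-deterministic
  expect_identical(as.numeric(synth_ecg(rr, m, 100)), as.numeric(ecg))
})

test_that("PPG lags ECG by the pulse transit time", {
  m <- morphology_spec(noise_sd = 0, ptt = 0.25)
  rr <- simulate_rr(rhythm_spec("AF", mean_hr = 70, seed = 4), 30)
  ecg <- as.numeric(synth_ecg(rr, m, 100))
  ppg <- as.numeric(synth_ppg(rr, m, 100))
  cc <- ccf(ppg, ecg, lag.max = 50, plot = FALSE)
  expect_lt(abs(cc$lag[which.max(cc$acf)] - 25), 2.5)

  # zero transit time: first systolic peak lands within one pulse width of
  # the first R peak
  m0 <- morphology_spec(noise_sd = 0, ptt = 0)
  ppg0 <- synth_ppg(rep(1, 5), m0, 100)
  ecg0 <- synth_ecg(rep(1, 5), m0, 100)
  p0 <- detect_ppg_peaks(as.numeric(ppg0), 100)
  expect_lt(min(abs((p0$peak_indices[1] - 1) / 100 - attr(ecg0, "beat_times"))),
            m0$ppg_sys_width * 4)
})

test_that("cohorts have the requested composition and are seed-reproducible", {
  co <- make_cohort(10, 0.5, 30, seed = 7)
  expect_length(co, 10)
  expect_equal(sum(vapply(co, function(r) r$rhythm_label == "AF", logical(1))), 5)
  expect_true(all(vapply(co, function(r) length(r$ecg) == 3000, logical(1))))
  expect_true(all(vapply(co, function(r) length(r$ppg) == 3000, logical(1))))
  # amplitudes normalized to [-1, 1]
  expect_true(all(vapply(co, function(r) max(abs(r$ecg)) <= 1, logical(1))))
  # annotations cover the full extent
  expect_true(all(vapply(co, function(r)
    r$annotations$start[1] == 0 && r$annotations$end[1] == 3000, logical(1))))

  co2 <- make_cohort(10, 0.5, 30, seed = 7)
  expect_identical(co, co2)
  expect_error(make_cohort(10, 1.5, 30), "rhythm_mix")
  expect_error(make_cohort(10, 0.5, 0.1), "duration")
})

test_that("waveform_record validates channel lengths and annotations", {
  expect_error(waveform_record(rnorm(100), rnorm(99), 100, "SR"), "equal length")
  expect_error(waveform_record(rnorm(100), NULL, 100, "SR",
                               annotations = data.frame(start = 0, end = 200,
                                                        rhythm = "SR")),
               "within")
  overlapping <- data.frame(start = c(0, 30), end = c(50, 80),
                            rhythm = c("SR", "AF"))
  expect_error(waveform_record(rnorm(100), NULL, 100, "mixed",
                               annotations = overlapping), "non-overlapping")
})

test_that("record CSV round trip preserves channels and annotations", {
  rec <- clean_record(seed = 12)
  dir <- withr::local_tempdir()
  write_record(rec, dir)
  back <- read_record(dir, rec$subject_id)
  expect_equal(back$ecg, rec$ecg)
  expect_equal(back$ppg, rec$ppg)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$annotations$rhythm, rec$annotations$rhythm)
})
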