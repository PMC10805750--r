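# Shared helpers for building small synthetic fixtures in code.

# Paired 30-s parent segments (PPG + ECG) from a simulated cohort.
cohort_pairs <- function(n_records, af_frac = 0.5, duration_s = 30, seed = 1,
                         id_prefix = "S") {
  co <- make_cohort(n_records, af_frac, duration_s, seed = seed,
                    id_prefix = id_prefix)
  stores <- lapply(co, function(r) segment_annotated(r, r$rhythm_label))
  do.call(bind_stores, stores)
}

# A clean single-rhythm record with known RR ground truth attached.
clean_record <- function(rhythm = "AF", mean_hr = 80, duration_s = 30,
                         seed = 1, fs = 100, noise_sd = 0.02, ptt = 0.2) {
  spec <- rhythm_spec(rhythm, mean_hr = mean_hr, seed = seed)
  rr <- simulate_rr(spec, ceiling(duration_s * mean_hr / 60 * 1.6) + 10)
  m <- morphology_spec(noise_sd = noise_sd, ptt = ptt)
  n <- round(fs * duration_s)
  set.seed(seed + 1)
  ecg <- synth_ecg(rr, m, fs)
  ppg <- synth_ppg(rr, m, fs)
  rec <- waveform_record(minmax_scale(ecg[seq_len(n)]), minmax_scale(ppg[seq_len(n)]),
                         fs, rhythm, subject_id = sprintf("C%d", seed))
  rec$rr <- rr
  rec$beat_times <- attr(ecg, "beat_times")
  rec$pulse_times <- attr(ppg, "pulse_times")
  rec
}
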