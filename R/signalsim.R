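#' Rhythm specification for the waveform simulator
#'
#' Describes the beat-to-beat interval statistics of a simulated record.
#' Sinus rhythm (SR) produces near-regular RR intervals modulated
#' sinusoidally by respiration (respiratory sinus arrhythmia); atrial
#' fibrillation (AF) produces serially uncorrelated RR intervals with a
#' configurable coefficient of variation, emulating the irregular
#' pulse-to-pulse timing that characterizes the arrhythmia.
#'
#' @param rhythm `"SR"` or `"AF"`.
#' @param mean_hr mean heart rate in beats/min, must lie in `[30, 220]`.
#' @param sr_rsa_depth fractional amplitude of respiratory RR modulation
#'   (SR only).
#' @param sr_rsa_freq respiratory modulation frequency in Hz (SR only).
#' @param sr_jitter_frac standard deviation of beat-level jitter as a
#'   fraction of the mean RR (SR only).
#' @param af_cv coefficient of variation of the AF RR distribution; must
#'   exceed the SR-equivalent RR variability.
#' @param seed integer seed; the same spec and seed always reproduce the
#'   same record.
#' @return an object of class `rhythm_spec`.
#' @export
rhythm_spec <- function(rhythm = c("SR", "AF"), mean_hr = if (rhythm == "AF") 85 else 70,
                        sr_rsa_depth = 0.08, sr_rsa_freq = 0.25,
                        sr_jitter_frac = 0.02, af_cv = 0.2, seed = 1L) {
  rhythm <- match.arg(rhythm)
  if (!is.numeric(mean_hr) || length(mean_hr) != 1L || mean_hr < 30 || mean_hr > 220)
    stop("mean_hr must be a single value in [30, 220]")
  if (af_cv <= 0 || sr_rsa_depth < 0 || sr_rsa_freq <= 0 || sr_jitter_frac < 0)
    stop("invalid rhythm_spec parameters")
  structure(list(rhythm = rhythm, mean_hr = mean_hr,
                 sr_rsa_depth = sr_rsa_depth, sr_rsa_freq = sr_rsa_freq,
                 sr_jitter_frac = sr_jitter_frac, af_cv = af_cv,
                 seed = as.integer(seed)),
            class = "rhythm_spec")
}

#' Waveform morphology specification
#'
#' Parametrizes the ECG beat template (sum of Gaussian bumps for the
#' P, Q, R, S and T waves), the PPG pulse template (systolic peak plus a
#' dicrotic wave), the pulse-transit-time delay between the ECG R-peak and
#' the corresponding PPG pulse, and additive measurement noise.
#'
#' `ecg_waves` is a data frame with columns `wave`, `amp` (signal units),
#' `offset` (bump center in seconds relative to the R peak; negative before)
#' and `width` (Gaussian SD in seconds). The complex rides at fixed
#' latencies around each R peak — the inter-beat baseline stretches with the
#' RR interval, the complex itself does not — except that the T wave is
#' pulled in on very short beats, mimicking rate-dependent QT shortening.
#' The R wave must have the strictly largest absolute amplitude.
#'
#' @param ecg_waves ECG bump table; the default is a textbook P-QRS-T shape.
#' @param ppg_sys_amp,ppg_sys_width systolic pulse amplitude and Gaussian SD
#'   (seconds).
#' @param ppg_dic_amp,ppg_dic_offset,ppg_dic_width dicrotic wave amplitude,
#'   delay after the systolic peak (seconds) and Gaussian SD (seconds).
#' @param ptt pulse transit time in seconds (delay from R-peak to systolic
#'   peak); must be non-negative.
#' @param noise_sd SD of additive white Gaussian noise, in signal units
#'   before per-record rescaling.
#' @return an object of class `morphology_spec`.
#' @export
morphology_spec <- function(ecg_waves = default_ecg_waves(),
                            ppg_sys_amp = 1.0, ppg_sys_width = 0.09,
                            ppg_dic_amp = 0.25, ppg_dic_offset = 0.28,
                            ppg_dic_width = 0.11,
                            ptt = 0.2, noise_sd = 0.02) {
  stopifnot(is.data.frame(ecg_waves),
            all(c("wave", "amp", "offset", "width") %in% names(ecg_waves)))
  r_amp <- abs(ecg_waves$amp[ecg_waves$wave == "R"])
  if (length(r_amp) != 1L || any(abs(ecg_waves$amp[ecg_waves$wave != "R"]) >= r_amp))
    stop("the R wave must have the strictly largest absolute amplitude")
  if (ptt < 0) stop("ptt must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(ecg_waves = ecg_waves,
                 ppg_sys_amp = ppg_sys_amp, ppg_sys_width = ppg_sys_width,
                 ppg_dic_amp = ppg_dic_amp, ppg_dic_offset = ppg_dic_offset,
                 ppg_dic_width = ppg_dic_width,
                 ptt = ptt, noise_sd = noise_sd),
            class = "morphology_spec")
}

#' @rdname morphology_spec
#' @export
default_ecg_waves <- function() {
  data.frame(wave   = c("P", "Q", "R", "S", "T"),
             amp    = c(0.15, -0.10, 1.00, -0.20, 0.30),
             offset = c(-0.160, -0.035, 0.000, 0.035, 0.280),
             width  = c(0.040, 0.012, 0.016, 0.014, 0.070))
}

#' Simulate a beat-to-beat RR interval series
#'
#' SR intervals follow `60/mean_hr` modulated sinusoidally at the
#' respiratory frequency plus small Gaussian jitter. AF intervals are drawn
#' i.i.d. from a log-normal distribution with mean `60/mean_hr` and
#' coefficient of variation `af_cv`, giving the serially uncorrelated,
#' highly irregular series typical of the arrhythmia.
#'
#' @param spec a [rhythm_spec()].
#' @param n_beats number of intervals to draw (>= 1).
#' @return numeric vector of `n_beats` positive RR intervals in seconds.
#' @export
simulate_rr <- function(spec, n_beats) {
  stopifnot(inherits(spec, "rhythm_spec"))
  if (!is.numeric(n_beats) || length(n_beats) != 1L || n_beats < 1)
    stop("n_beats must be a positive count")
  n_beats <- as.integer(n_beats)
  base <- 60 / spec$mean_hr
  with_seed(spec$seed, {
    if (spec$rhythm == "SR") {
      rr <- numeric(n_beats)
      t_cur <- 0
      jit <- rnorm(n_beats, 0, spec$sr_jitter_frac * base)
      for (i in seq_len(n_beats)) {
        rr[i] <- base * (1 + spec$sr_rsa_depth * sin(2 * pi * spec$sr_rsa_freq * t_cur)) + jit[i]
        rr[i] <- max(rr[i], 0.25 * base)
        t_cur <- t_cur + rr[i]
      }
      rr
    } else {
      sdlog <- sqrt(log(1 + spec$af_cv^2))
      meanlog <- log(base) - sdlog^2 / 2
      pmax(rlnorm(n_beats, meanlog, sdlog), 0.2)
    }
  })
}

# Add Gaussian bumps (centers/widths in seconds) to a sampled signal.
add_bumps <- function(x, fs, centers, amps, widths) {
  n <- length(x)
  for (j in seq_along(centers)) {
    w <- widths[j]
    i0 <- max(1L, floor((centers[j] - 4 * w) * fs) + 1L)
    i1 <- min(n, ceiling((centers[j] + 4 * w) * fs) + 1L)
    if (i0 > i1) next
    tt <- (seq(i0, i1) - 1) / fs
    x[i0:i1] <- x[i0:i1] + amps[j] * exp(-(tt - centers[j])^2 / (2 * w^2))
  }
  x
}

#' Synthesize an ECG waveform from an RR series
#'
#' One P-QRS-T complex (a sum of Gaussian bumps per [morphology_spec()]) is
#' placed per RR interval, its R peak at `S_{k-1} + 0.2` s with
#' `S_k = sum(rr[1:k])`, so consecutive R peaks are separated by exactly the
#' generating RR intervals. Bumps sit at fixed latencies around the R peak;
#' the T wave is pulled in to `0.55 * rr` on beats too short for its
#' nominal latency. The R-peak times are attached as attribute
#' `"beat_times"` so detector accuracy can be scored against exact ground
#' truth.
#'
#' @param rr positive RR intervals in seconds.
#' @param morph a [morphology_spec()].
#' @param fs sampling rate in Hz.
#' @return numeric vector of length `round(fs * sum(rr))` with attribute
#'   `beat_times` (R-peak times in seconds).
#' @export
synth_ecg <- function(rr, morph = morphology_spec(), fs = 100) {
  stopifnot(inherits(morph, "morphology_spec"))
  if (fs <= 0) stop("fs must be positive")
  if (length(rr) < 1 || any(rr <= 0)) stop("rr must be a nonempty positive vector")
  n <- round(fs * sum(rr))
  r_times <- cumsum(c(0, rr[-length(rr)])) + 0.2
  x <- numeric(n)
  wv <- morph$ecg_waves
  clamped <- FALSE
  for (k in seq_along(rr)) {
    off <- wv$offset
    t_row <- wv$wave == "T"
    off[t_row] <- min(off[t_row], 0.55 * rr[k])   # rate-dependent QT
    widths <- wv$width
    if (rr[k] < 0.25) {
      widths <- pmin(widths, rr[k] / 4)
      clamped <- TRUE
    }
    x <- add_bumps(x, fs, r_times[k] + off, wv$amp, widths)
  }
  if (clamped) warning("short beat(s): ECG bump widths clamped to fit the interval")
  if (morph$noise_sd > 0) x <- x + rnorm(n, 0, morph$noise_sd)
  attr(x, "beat_times") <- r_times
  x
}

#' Synthesize a PPG waveform paired with an ECG
#'
#' One systolic pulse plus a dicrotic wave per beat, with the systolic peak
#' delayed by the pulse transit time `ptt` relative to the corresponding
#' R-peak. The output has the same length as the ECG synthesized from the
#' same RR series at the same rate.
#'
#' @inheritParams synth_ecg
#' @return numeric vector of length `round(fs * sum(rr))` with attribute
#'   `pulse_times` (systolic peak times in seconds; pulses falling past the
#'   end of the record are dropped from the attribute).
#' @export
synth_ppg <- function(rr, morph = morphology_spec(), fs = 100) {
  stopifnot(inherits(morph, "morphology_spec"))
  if (fs <= 0) stop("fs must be positive")
  if (length(rr) < 1 || any(rr <= 0)) stop("rr must be a nonempty positive vector")
  n <- round(fs * sum(rr))
  r_times <- cumsum(c(0, rr[-length(rr)])) + 0.2
  sys_t <- r_times + morph$ptt
  dic_t <- sys_t + morph$ppg_dic_offset
  x <- numeric(n)
  x <- add_bumps(x, fs, sys_t, rep(morph$ppg_sys_amp, length(sys_t)),
                 rep(morph$ppg_sys_width, length(sys_t)))
  x <- add_bumps(x, fs, dic_t, rep(morph$ppg_dic_amp, length(dic_t)),
                 rep(morph$ppg_dic_width, length(dic_t)))
  if (morph$noise_sd > 0) x <- x + rnorm(n, 0, morph$noise_sd)
  attr(x, "pulse_times") <- sys_t[sys_t < n / fs]
  x
}

#' Paired ECG/PPG waveform record
#'
#' The unit of ingestion: equal-length ECG and PPG sample arrays, a sampling
#' rate, a rhythm label and a table of half-open rhythm annotation intervals
#' in sample coordinates (0-based `[start, end)`).
#'
#' @param ecg,ppg numeric sample vectors; `ppg` may be `NULL`.
#' @param fs sampling rate (Hz).
#' @param rhythm_label `"SR"`, `"AF"` or `"mixed"`.
#' @param subject_id character identifier.
#' @param annotations data frame with columns `start`, `end`, `rhythm`;
#'   intervals must be sorted, non-overlapping and within `[0, length(ecg))`.
#' @return object of class `waveform_record`.
#' @export
waveform_record <- function(ecg, ppg = NULL, fs, rhythm_label, subject_id = "S000",
                            annotations = NULL) {
  if (fs <= 0) stop("fs must be positive")
  if (!is.null(ppg) && length(ppg) != length(ecg))
    stop("ecg and ppg must have equal length")
  if (is.null(annotations))
    annotations <- data.frame(start = 0L, end = length(ecg), rhythm = rhythm_label)
  stopifnot(all(c("start", "end", "rhythm") %in% names(annotations)))
  if (nrow(annotations) > 0) {
    if (any(annotations$start < 0) || any(annotations$end > length(ecg)) ||
        any(annotations$end <= annotations$start))
      stop("annotation intervals must be non-empty and within [0, length)")
    if (is.unsorted(annotations$start) ||
        any(annotations$start[-1] < annotations$end[-nrow(annotations)]))
      stop("annotation intervals must be sorted and non-overlapping")
  }
  structure(list(ecg = as.numeric(ecg), ppg = if (is.null(ppg)) NULL else as.numeric(ppg),
                 fs = fs, rhythm_label = rhythm_label, subject_id = subject_id,
                 annotations = annotations),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record> %s: %d samples @ %g Hz, rhythm %s, PPG %s\n",
              x$subject_id, length(x$ecg), x$fs, x$rhythm_label,
              if (is.null(x$ppg)) "absent" else "present"))
  invisible(x)
}

#' Simulate a cohort of paired ECG/PPG records
#'
#' Generates `n_records` fixed-duration records, a seeded mix of AF and SR
#' rhythms, each with its own heart rate, pulse transit time and RR series
#' drawn from per-record seeds derived deterministically from the cohort
#' seed. Both channels are min-max scaled to `[-1, 1]` per record, matching
#' the input normalization of the translation network.
#'
#' @param n_records number of records (>= 1).
#' @param rhythm_mix fraction of AF records in `[0, 1]`; the AF count is
#'   `round(n_records * rhythm_mix)`.
#' @param duration_s record duration in seconds.
#' @param seed cohort seed.
#' @param fs sampling rate (Hz).
#' @param morph a [morphology_spec()]; `ptt` is redrawn per record in
#'   `ptt_range` to emulate subject-to-subject transit-time differences.
#' @param ptt_range length-2 range of per-record pulse transit times (s).
#' @param hr_range_sr,hr_range_af per-rhythm ranges from which each record's
#'   mean heart rate is drawn (beats/min).
#' @param id_prefix prefix for subject identifiers; give different cohorts
#'   different prefixes so parent identifiers stay globally unique.
#' @return list of [waveform_record()] objects.
#' @export
make_cohort <- function(n_records, rhythm_mix = 0.5, duration_s = 30, seed = 1L,
                        fs = 100, morph = morphology_spec(),
                        ptt_range = c(0.18, 0.28),
                        hr_range_sr = c(55, 85), hr_range_af = c(65, 110),
                        id_prefix = "S") {
  if (n_records < 1) stop("n_records must be >= 1")
  if (rhythm_mix < 0 || rhythm_mix > 1) stop("rhythm_mix must be in [0, 1]")
  if (duration_s < 60 / 220) stop("duration_s shorter than one beat")
  n_af <- round(n_records * rhythm_mix)
  rhythms <- c(rep("AF", n_af), rep("SR", n_records - n_af))
  n_target <- round(fs * duration_s)
  lapply(seq_len(n_records), function(i) {
    rec_seed <- derive_seed(seed, paste0("record", i))
    rhythm <- rhythms[i]
    with_seed(rec_seed, {
      hr <- if (rhythm == "AF") runif(1, hr_range_af[1], hr_range_af[2])
            else runif(1, hr_range_sr[1], hr_range_sr[2])
      ptt <- runif(1, ptt_range[1], ptt_range[2])
      spec <- rhythm_spec(rhythm, mean_hr = hr, seed = derive_seed(rec_seed, "rr"))
      n_beats <- ceiling(duration_s * hr / 60 * 1.6) + 10
      rr <- simulate_rr(spec, n_beats)
      while (sum(rr) < duration_s + 2) {
        spec2 <- rhythm_spec(rhythm, mean_hr = hr, seed = derive_seed(rec_seed, "rr-extra"))
        rr <- c(rr, simulate_rr(spec2, n_beats))
      }
      m <- morph
      m$ptt <- ptt
      ecg <- synth_ecg(rr, m, fs)
      ppg <- synth_ppg(rr, m, fs)
      ecg <- minmax_scale(ecg[seq_len(n_target)])
      ppg <- minmax_scale(ppg[seq_len(n_target)])
      waveform_record(ecg, ppg, fs, rhythm,
                      subject_id = sprintf("%s%03d", id_prefix, i),
                      annotations = data.frame(start = 0L, end = n_target,
                                               rhythm = rhythm))
    })
  })
}
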