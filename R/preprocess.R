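#' Ordered beat locations for one channel
#'
#' @param peak_indices strictly increasing 1-based sample positions;
#'   fractional positions (sub-sample peak refinement) are allowed.
#' @param fs sampling rate (Hz).
#' @param channel `"ECG"` or `"PPG"`.
#' @return object of class `beat_series` with an `intervals()` accessor via
#'   [beat_intervals()].
#' @export
beat_series <- function(peak_indices, fs, channel = c("ECG", "PPG")) {
  channel <- match.arg(channel)
  peak_indices <- as.numeric(peak_indices)
  if (length(peak_indices) > 1 && any(diff(peak_indices) <= 0))
    stop("peak indices must be strictly increasing")
  if (fs <= 0) stop("fs must be positive")
  structure(list(peak_indices = peak_indices, fs = fs, channel = channel),
            class = "beat_series")
}

#' Inter-beat intervals of a beat series, in seconds
#' @param b a [beat_series()].
#' @return numeric vector of positive intervals (length `n_peaks - 1`).
#' @export
beat_intervals <- function(b) {
  stopifnot(inherits(b, "beat_series"))
  diff(b$peak_indices) / b$fs
}

#' Resample a waveform record to a target rate
#'
#' Rational-factor polyphase resampling of both channels; annotation indices
#' are mapped proportionally, rounded toward the interval interior (starts
#' up, ends down) so that re-indexed annotations never spill outside their
#' original extent.
#'
#' @param record a [waveform_record()].
#' @param fs_target target sampling rate (Hz); may be above or below the
#'   record's rate.
#' @return a [waveform_record()] at `fs_target`.
#' @export
resample_record <- function(record, fs_target) {
  stopifnot(inherits(record, "waveform_record"))
  if (fs_target <= 0) stop("fs_target must be positive")
  if (length(record$ecg) == 0) stop("cannot resample a zero-length record")
  if (fs_target == record$fs) return(record)
  frac <- rational_fraction(fs_target / record$fs)
  n_in <- length(record$ecg)
  n_out <- round(n_in * fs_target / record$fs)
  p <- frac$p; q <- frac$q
  # zero-stuff by p, zero-phase FIR low-pass at the tighter Nyquist, take
  # every q-th sample: no group delay, so resampled peaks stay aligned
  taps <- 2L * 10L * max(p, q)
  h <- signal::fir1(taps, 1 / max(p, q))
  pad <- q * min((n_in - 1) %/% q, 10)   # reflect margin, multiple of q
  res <- function(x) {
    xp <- c(rev(x[seq_len(pad) + 1]), x, rev(x[n_in - seq_len(pad)]))
    up <- numeric(length(xp) * p)
    up[seq(1, by = p, length.out = length(xp))] <- xp * p
    yf <- as.numeric(signal::filtfilt(h, up))
    y <- yf[seq(pad * p + 1, length(yf), by = q)]
    if (length(y) >= n_out) y[seq_len(n_out)] else c(y, rep(y[length(y)], n_out - length(y)))
  }
  ecg <- res(record$ecg)
  ppg <- if (is.null(record$ppg)) NULL else res(record$ppg)
  ratio <- fs_target / record$fs
  ann <- record$annotations
  if (nrow(ann) > 0) {
    ann$start <- pmin(ceiling(ann$start * ratio), n_out)
    ann$end <- pmax(pmin(floor(ann$end * ratio), n_out), ann$start)
    ann <- ann[ann$end > ann$start, , drop = FALSE]
  }
  waveform_record(ecg, ppg, fs_target, record$rhythm_label, record$subject_id, ann)
}

# Smallest integer fraction p/q equal to `ratio` (up to 1e-9).
rational_fraction <- function(ratio, max_den = 10000L) {
  for (q in seq_len(max_den)) {
    p <- ratio * q
    if (abs(p - round(p)) < 1e-9) return(list(p = as.integer(round(p)), q = q))
  }
  stop("sampling-rate ratio cannot be expressed as a small rational number")
}

#' Detect ECG R-peaks with the Pan-Tompkins algorithm
#'
#' The classic QRS detector: zero-phase band-pass at 5-15 Hz, five-point
#' derivative, squaring, 150-ms moving-window integration, then adaptive
#' signal/noise thresholding with a 200-ms refractory period. Thresholds are
#' learned from the first two seconds. Each accepted detection is refined to
#' the absolute maximum of the band-passed signal in a short window, which
#' places it on the R wave itself.
#'
#' @param ecg numeric sample vector.
#' @param fs sampling rate (Hz).
#' @param refractory_s refractory period between QRS detections (seconds).
#' @param learn_s length of the threshold learning phase (seconds).
#' @return a [beat_series()]; empty when the signal is shorter than 2 s or
#'   contains no detectable QRS energy.
#' @export
detect_r_peaks <- function(ecg, fs, refractory_s = 0.2, learn_s = 2) {
  n <- length(ecg)
  if (n < 2 * fs || all(ecg == ecg[1]))
    return(beat_series(integer(0), fs, "ECG"))
  bp <- tryCatch({
    bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
    as.numeric(signal::filtfilt(bf, ecg))
  }, error = function(e) ecg - mean(ecg))
  # five-point derivative (zero-phase alignment by symmetric shift)
  d <- c(0, 0, (2 * bp[5:n] + bp[4:(n - 1)] - bp[2:(n - 3)] - 2 * bp[1:(n - 4)]) / 8, 0, 0)
  sq <- d^2
  w <- max(1L, round(0.15 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0
  refr <- max(1L, round(refractory_s * fs))
  cand <- local_maxima(mwi, min_height = .Machine$double.eps, min_dist = refr)
  if (length(cand) == 0) return(beat_series(integer(0), fs, "ECG"))
  learn_n <- min(n, max(2L, round(learn_s * fs)))
  spki <- max(mwi[seq_len(learn_n)])
  npki <- mean(mwi[seq_len(learn_n)]) / 2
  thr <- npki + 0.25 * (spki - npki)
  accepted <- integer(0)
  for (i in cand) {
    if (mwi[i] > thr) {
      accepted <- c(accepted, i)
      spki <- 0.125 * mwi[i] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
    thr <- npki + 0.25 * (spki - npki)
  }
  if (length(accepted) == 0) return(beat_series(integer(0), fs, "ECG"))
  # refine: absolute band-passed maximum near the integration peak
  half <- as.integer(round(0.12 * fs))
  r_locs <- vapply(accepted, function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    as.integer(lo + which.max(abs(bp[lo:hi])) - 1L)
  }, integer(1))
  r_locs <- sort(unique(r_locs))
  if (length(r_locs) > 1) r_locs <- r_locs[c(TRUE, diff(r_locs) > refr / 2)]
  # drop detections so close to the record edge that the QRS is truncated
  r_locs <- r_locs[r_locs > 0.1 * fs & r_locs <= n - 0.1 * fs]
  beat_series(refine_peaks(abs(bp), r_locs), fs, "ECG")
}

# Parabolic (three-point) sub-sample refinement of peak positions: fit a
# quadratic through the peak sample and its neighbours and take its vertex.
refine_peaks <- function(x, idx) {
  n <- length(x)
  vapply(idx, function(i) {
    if (i <= 1 || i >= n) return(as.numeric(i))
    denom <- x[i - 1] - 2 * x[i] + x[i + 1]
    if (denom >= 0) return(as.numeric(i))
    off <- 0.5 * (x[i - 1] - x[i + 1]) / denom
    i + max(-0.5, min(0.5, off))
  }, numeric(1))
}

# Local maxima above a height floor, thinned to a minimum spacing by
# keeping the tallest peak in each conflict (greedy, height-ordered).
local_maxima <- function(x, min_height, min_dist) {
  n <- length(x)
  if (n < 3) return(integer(0))
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
               x[2:(n - 1)] >= min_height) + 1L
  if (length(idx) == 0) return(integer(0))
  ord <- idx[order(x[idx], decreasing = TRUE)]
  keep <- logical(n)
  blocked <- logical(n)
  for (i in ord) {
    if (blocked[i]) next
    keep[i] <- TRUE
    lo <- max(1L, i - min_dist)
    hi <- min(n, i + min_dist)
    blocked[lo:hi] <- TRUE
  }
  which(keep)
}

#' Detect PPG systolic peaks
#'
#' Local-maximum detection with a relative height floor (excluding the
#' lower-amplitude dicrotic wave) and a minimum inter-peak distance of
#' `60 / max_hr` seconds.
#'
#' @param ppg numeric sample vector.
#' @param fs sampling rate (Hz).
#' @param max_hr physiological ceiling used for the distance floor
#'   (beats/min).
#' @param height_frac height floor as a fraction of the signal range above
#'   its minimum.
#' @return a [beat_series()]; empty for flat or too-short signals.
#' @export
detect_ppg_peaks <- function(ppg, fs, max_hr = 220, height_frac = 0.55,
                             lowpass_hz = 10) {
  n <- length(ppg)
  if (n < 2 * fs || all(ppg == ppg[1]))
    return(beat_series(integer(0), fs, "PPG"))
  x <- ppg
  if (!is.null(lowpass_hz) && lowpass_hz < fs / 2) {
    # zero-phase low-pass: the systolic peak is broad, so measurement noise
    # otherwise dominates the peak location
    x <- tryCatch({
      bf <- signal::butter(3, lowpass_hz / (fs / 2), type = "low")
      as.numeric(signal::filtfilt(bf, ppg))
    }, error = function(e) ppg)
  }
  rng <- range(x)
  if (rng[2] == rng[1]) return(beat_series(integer(0), fs, "PPG"))
  min_h <- rng[1] + height_frac * (rng[2] - rng[1])
  min_dist <- max(1L, round(60 / max_hr * fs))
  locs <- local_maxima(x, min_h, min_dist)
  # a pulse truncated by the record edge peaks at the wrong place; drop it
  locs <- locs[locs > 0.3 * fs & locs <= n - 0.3 * fs]
  beat_series(refine_peaks(x, locs), fs, "PPG")
}

#' Correlation between two channels' inter-peak interval sequences
#'
#' The Pearson correlation of the inter-beat interval series (not the raw
#' peak index arrays, which are trivially near-collinear), truncated to the
#' common interval count. This carries the rhythm information the
#' quality-control screen targets: channels driven by the same heart rhythm
#' give values near 1 even when one is delayed by the pulse transit time.
#'
#' @param a,b [beat_series()] objects (any channel order).
#' @return correlation in `[-1, 1]`, or `NA` when either series has fewer
#'   than 3 peaks or an interval sequence is constant.
#' @export
interval_correlation <- function(a, b) {
  stopifnot(inherits(a, "beat_series"), inherits(b, "beat_series"))
  if (length(a$peak_indices) < 3 || length(b$peak_indices) < 3) return(NA_real_)
  ia <- beat_intervals(a)
  ib <- beat_intervals(b)
  m <- min(length(ia), length(ib))
  ia <- ia[seq_len(m)]
  ib <- ib[seq_len(m)]
  if (sd(ia) == 0 || sd(ib) == 0) return(NA_real_)
  max(-1, min(1, cor(ia, ib)))
}

#' Quality-control screen for a paired record
#'
#' A record is kept only when (a) the correlation between its ECG R-R
#' intervals and PPG pulse intervals exceeds `threshold` (skipped when the
#' record has no PPG), and (b) the mean heart rate detected on the ECG is at
#' least `hr_floor` — a low detected rate on a continuous recording signals
#' a channel too noisy for peak detection rather than true bradycardia.
#' Failures are reported, never raised.
#'
#' @param record a [waveform_record()].
#' @param threshold minimum interval correlation (default 0.96).
#' @param hr_floor minimum mean detected heart rate (beats/min, default 30).
#' @return a `qc_report` list: `interval_correlation`, `mean_hr`, `passed`,
#'   `reasons`.
#' @export
qc_screen <- function(record, threshold = 0.96, hr_floor = 30) {
  stopifnot(inherits(record, "waveform_record"))
  reasons <- character(0)
  r <- detect_r_peaks(record$ecg, record$fs)
  mean_hr <- if (length(r$peak_indices) >= 2) 60 / mean(beat_intervals(r)) else 0
  if (mean_hr < hr_floor)
    reasons <- c(reasons, sprintf("mean detected HR %.1f bpm below floor %g", mean_hr, hr_floor))
  icorr <- NA_real_
  if (!is.null(record$ppg)) {
    p <- detect_ppg_peaks(record$ppg, record$fs)
    icorr <- interval_correlation(r, p)
    if (is.na(icorr))
      reasons <- c(reasons, "too few peaks for interval correlation")
    else if (icorr <= threshold)
      reasons <- c(reasons, sprintf("interval correlation %.3f not above %g", icorr, threshold))
  }
  structure(list(interval_correlation = icorr, mean_hr = mean_hr,
                 passed = length(reasons) == 0, reasons = reasons),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> passed=%s, interval_correlation=%s, mean_hr=%.1f bpm\n",
              x$passed, format(x$interval_correlation, digits = 4), x$mean_hr))
  for (r in x$reasons) cat(" -", r, "\n")
  invisible(x)
}

#' Fixed-length labeled segment container
#'
#' Holds equal-length waveform segments as matrix rows together with
#' per-segment rhythm labels, real/generated provenance, and the identifier
#' of the parent segment each row came from (used for leakage-safe
#' train/test splitting). An optional paired ECG matrix carries the matching
#' ECG channel for translation training.
#'
#' @param segments numeric matrix, one segment per row.
#' @param labels character/factor vector (`"AF"`/`"SR"`), one per row.
#' @param origin `"real"` or `"generated"`, one per row (recycled).
#' @param parent_id character vector, one per row.
#' @param fs sampling rate (Hz).
#' @param segment_seconds nominal segment duration (s).
#' @param ecg optional matrix of paired ECG segments, same shape.
#' @return object of class `segment_store`.
#' @export
segment_store <- function(segments, labels, origin = "real", parent_id = NULL,
                          fs = 100, segment_seconds = ncol(segments) / fs,
                          ecg = NULL) {
  segments <- as.matrix(segments)
  n <- nrow(segments)
  origin <- rep_len(origin, n)
  if (is.null(parent_id)) parent_id <- sprintf("seg%05d", seq_len(n))
  if (length(labels) != n || length(parent_id) != n)
    stop("labels and parent_id must match the segment count")
  if (!is.null(ecg)) {
    ecg <- as.matrix(ecg)
    if (!all(dim(ecg) == dim(segments))) stop("paired ecg matrix must match segments")
  }
  structure(list(segments = segments, labels = as.character(labels),
                 origin = origin, parent_id = as.character(parent_id),
                 fs = fs, segment_seconds = segment_seconds, ecg = ecg),
            class = "segment_store")
}

#' @export
print.segment_store <- function(x, ...) {
  cat(sprintf("<segment_store> %d segments x %d samples @ %g Hz (%g s)%s\n",
              nrow(x$segments), ncol(x$segments), x$fs, x$segment_seconds,
              if (is.null(x$ecg)) "" else ", paired ECG"))
  print(table(label = x$labels, origin = x$origin))
  invisible(x)
}

#' Number of segments in a store
#' @param store a [segment_store()].
#' @return integer count.
#' @export
n_segments <- function(store) nrow(store$segments)

#' Concatenate segment stores with identical geometry
#' @param ... [segment_store()] objects (NULLs are dropped).
#' @return a combined [segment_store()]; the paired ECG matrix is kept only
#'   when every input carries one.
#' @export
bind_stores <- function(...) {
  stores <- list(...)
  stores <- stores[!vapply(stores, is.null, logical(1))]
  stopifnot(length(stores) > 0)
  L <- unique(vapply(stores, function(s) ncol(s$segments), numeric(1)))
  fs <- unique(vapply(stores, function(s) s$fs, numeric(1)))
  if (length(L) != 1 || length(fs) != 1) stop("stores have mismatched geometry")
  has_ecg <- vapply(stores, function(s) !is.null(s$ecg), logical(1))
  segment_store(do.call(rbind, lapply(stores, `[[`, "segments")),
                unlist(lapply(stores, `[[`, "labels")),
                unlist(lapply(stores, `[[`, "origin")),
                unlist(lapply(stores, `[[`, "parent_id")),
                fs = fs, segment_seconds = stores[[1]]$segment_seconds,
                ecg = if (all(has_ecg)) do.call(rbind, lapply(stores, `[[`, "ecg")) else NULL)
}

#' Row-subset a segment store
#' @param store a [segment_store()].
#' @param idx integer or logical row index.
#' @return a [segment_store()] with the selected rows.
#' @export
subset_store <- function(store, idx) {
  segment_store(store$segments[idx, , drop = FALSE], store$labels[idx],
                store$origin[idx], store$parent_id[idx],
                fs = store$fs, segment_seconds = store$segment_seconds,
                ecg = if (is.null(store$ecg)) NULL else store$ecg[idx, , drop = FALSE])
}

#' Cut rhythm-annotated regions into fixed-length segments
#'
#' Non-overlapping, left-aligned windows placed fully inside every
#' annotation interval whose rhythm matches; any remainder shorter than the
#' window is discarded, and no window ever crosses an annotation boundary.
#'
#' @param record a [waveform_record()].
#' @param rhythm rhythm to extract (`"AF"` or `"SR"`).
#' @param seconds window length (default 30 s).
#' @param origin provenance recorded on the output store.
#' @return a [segment_store()] of PPG segments with the paired ECG attached
#'   when the record has both channels (ECG-only records store the ECG as
#'   the segment matrix).
#' @export
segment_annotated <- function(record, rhythm, seconds = 30, origin = "real") {
  stopifnot(inherits(record, "waveform_record"))
  win <- round(record$fs * seconds)
  ann <- record$annotations
  ann <- ann[ann$rhythm == rhythm, , drop = FALSE]
  seg_ppg <- list(); seg_ecg <- list(); parents <- character(0)
  k <- 0L
  for (a in seq_len(nrow(ann))) {
    start <- ann$start[a]
    while (start + win <= ann$end[a]) {
      k <- k + 1L
      idx <- (start + 1L):(start + win)   # annotations are 0-based half-open
      seg_ecg[[k]] <- record$ecg[idx]
      if (!is.null(record$ppg)) seg_ppg[[k]] <- record$ppg[idx]
      parents <- c(parents, sprintf("%s_%s_%03d", record$subject_id, rhythm, k))
      start <- start + win
    }
  }
  if (k == 0L)
    return(segment_store(matrix(numeric(0), 0, win), character(0), character(0),
                         character(0), fs = record$fs, segment_seconds = seconds))
  ecg_m <- do.call(rbind, seg_ecg)
  if (is.null(record$ppg)) {
    segment_store(ecg_m, rep(rhythm, k), origin, parents,
                  fs = record$fs, segment_seconds = seconds)
  } else {
    segment_store(do.call(rbind, seg_ppg), rep(rhythm, k), origin, parents,
                  fs = record$fs, segment_seconds = seconds, ecg = ecg_m)
  }
}

#' Slice parent segments into overlapping sub-segments
#'
#' Each parent row yields windows of `slice_seconds` advanced by
#' `stride_seconds`. The sliding-window formula admits
#' `floor((segment_seconds - slice_seconds) / stride_seconds) + 1` windows;
#' in compatibility mode (the default) the final window — the one starting
#' exactly at `segment_seconds - slice_seconds` — is dropped whenever more
#' than one window exists, so a 30-s parent yields 15 slices of 15 s at a
#' 1-s stride. Labels, origins and parent identifiers are inherited.
#'
#' @param store a [segment_store()] of parents.
#' @param slice_seconds window length (s), at most `segment_seconds`.
#' @param stride_seconds positive stride (s).
#' @param drop_last drop the final full-coverage window (compatibility
#'   mode); default `TRUE`.
#' @return a [segment_store()] of slices.
#' @export
slice_segments <- function(store, slice_seconds = 15, stride_seconds = 1,
                           drop_last = TRUE) {
  stopifnot(inherits(store, "segment_store"))
  if (stride_seconds <= 0) stop("stride_seconds must be positive")
  if (slice_seconds > store$segment_seconds)
    stop("slice_seconds exceeds the parent segment length")
  fs <- store$fs
  win <- round(fs * slice_seconds)
  stride <- round(fs * stride_seconds)
  n_off <- floor((store$segment_seconds - slice_seconds) / stride_seconds) + 1
  if (drop_last && n_off > 1) n_off <- n_off - 1
  offs <- (seq_len(n_off) - 1L) * stride
  n <- nrow(store$segments)
  out <- matrix(0, n * n_off, win)
  out_ecg <- if (is.null(store$ecg)) NULL else matrix(0, n * n_off, win)
  row <- 0L
  for (i in seq_len(n)) {
    for (o in offs) {
      row <- row + 1L
      out[row, ] <- store$segments[i, (o + 1L):(o + win)]
      if (!is.null(out_ecg)) out_ecg[row, ] <- store$ecg[i, (o + 1L):(o + win)]
    }
  }
  segment_store(out, rep(store$labels, each = n_off),
                rep(store$origin, each = n_off),
                rep(store$parent_id, each = n_off),
                fs = fs, segment_seconds = slice_seconds, ecg = out_ecg)
}
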