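#' Percent root-mean-square difference
#'
#' `100 * sqrt( sum((ref - gen)^2) / sum((ref - mean(ref))^2) )`. The
#' default denominator is mean-centered (the convention of the
#' signal-compression literature the metric comes from); `centered = FALSE`
#' divides by the raw signal energy instead. A generated signal equal to
#' the reference scores 0; one stuck at the reference mean scores 100.
#'
#' @param ref,gen equal-length numeric vectors (length >= 2).
#' @param centered use the mean-centered denominator (default `TRUE`).
#' @return PRD in percent (>= 0).
#' @export
prd <- function(ref, gen, centered = TRUE) {
  if (length(ref) != length(gen) || length(ref) < 2)
    stop("ref and gen must be equal-length vectors of length >= 2")
  denom <- if (centered) sum((ref - mean(ref))^2) else sum(ref^2)
  if (denom == 0) stop("undefined PRD: reference has zero variance")
  100 * sqrt(sum((ref - gen)^2) / denom)
}

#' Pearson correlation between reference and generated signals
#'
#' @param ref,gen equal-length numeric vectors (length >= 2), both
#'   non-constant.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_cc <- function(ref, gen) {
  if (length(ref) != length(gen) || length(ref) < 2)
    stop("ref and gen must be equal-length vectors of length >= 2")
  if (sd(ref) == 0 || sd(gen) == 0)
    stop("undefined correlation: constant input")
  max(-1, min(1, cor(ref, gen)))
}

#' Beat-by-beat heart rate series from a waveform
#'
#' Detects beats (R-peaks for ECG, systolic peaks for PPG) and converts
#' each successive inter-beat interval to an instantaneous rate
#' `60 / interval`.
#'
#' @param x numeric sample vector.
#' @param fs sampling rate (Hz).
#' @param channel `"ECG"` or `"PPG"` — selects the detector.
#' @return numeric vector of heart rates in beats/min.
#' @export
beat_hr_series <- function(x, fs, channel = c("ECG", "PPG")) {
  channel <- match.arg(channel)
  b <- if (channel == "ECG") detect_r_peaks(x, fs) else detect_ppg_peaks(x, fs)
  if (length(b$peak_indices) < 3)
    stop(sprintf("fewer than 3 detectable beats on the %s channel", channel))
  60 / beat_intervals(b)
}

#' Heart-rate series from known beat intervals
#' @param intervals positive inter-beat intervals in seconds.
#' @return heart rates in beats/min.
#' @export
intervals_to_hr <- function(intervals) {
  stopifnot(all(intervals > 0))
  60 / intervals
}

#' Agreement between two beat-by-beat heart-rate series
#'
#' The series are truncated to their common length; the Pearson correlation
#' and a two-sided paired t-test on the differences are returned. Two
#' degenerate cases get conventional values: identical series give p = 1
#' (no evidence of a difference), and a constant nonzero difference gives
#' p = 0 (the difference is certain).
#'
#' @param ecg_hr,ppg_hr heart-rate series in beats/min (common length >= 3).
#' @return list with `correlation`, `t_statistic`, `p_value`, `n`.
#' @export
hr_agreement <- function(ecg_hr, ppg_hr) {
  m <- min(length(ecg_hr), length(ppg_hr))
  if (m < 3) stop("need at least 3 common beats")
  a <- ecg_hr[seq_len(m)]
  b <- ppg_hr[seq_len(m)]
  d <- b - a
  corr <- if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
  if (sd(d) == 0) {
    if (all(d == 0)) return(list(correlation = if (is.na(corr)) 1 else corr,
                                 t_statistic = 0, p_value = 1, n = m))
    return(list(correlation = corr, t_statistic = Inf * sign(mean(d)),
                p_value = 0, n = m))
  }
  tt <- t.test(b, a, paired = TRUE)
  list(correlation = corr, t_statistic = unname(tt$statistic),
       p_value = tt$p.value, n = m)
}

#' Per-segment morphology metrics between two stores
#'
#' Computes PRD and Pearson correlation for each (reference, generated)
#' segment pair.
#'
#' @param ref_store,gen_store [segment_store()] objects with identical
#'   geometry and row order.
#' @return data frame with columns `prd` and `cc`, one row per segment.
#' @export
segment_metrics <- function(ref_store, gen_store) {
  stopifnot(inherits(ref_store, "segment_store"), inherits(gen_store, "segment_store"))
  if (!all(dim(ref_store$segments) == dim(gen_store$segments)))
    stop("stores have mismatched geometry")
  n <- nrow(ref_store$segments)
  data.frame(
    prd = vapply(seq_len(n), function(i)
      prd(ref_store$segments[i, ], gen_store$segments[i, ]), numeric(1)),
    cc = vapply(seq_len(n), function(i)
      pearson_cc(ref_store$segments[i, ], gen_store$segments[i, ]), numeric(1)))
}

#' Summarize per-segment metrics with outlier flagging
#'
#' For each metric column, values beyond `mean +/- n_sd * SD` (computed
#' once on the full set) are flagged as outliers and excluded from the
#' reported mean and SD; the counts are reported, never silently dropped.
#' Set `n_sd = Inf` to disable flagging.
#'
#' @param metrics data frame from [segment_metrics()] (columns `prd`, `cc`).
#' @param n_sd outlier rule width in standard deviations (default 3).
#' @return a `metrics_report` list: `n_segments`, per-metric outlier counts,
#'   post-exclusion means and SDs.
#' @export
summarize_metrics <- function(metrics, n_sd = 3) {
  stopifnot(is.data.frame(metrics), nrow(metrics) > 0,
            all(c("prd", "cc") %in% names(metrics)))
  flag <- function(x) {
    if (!is.finite(n_sd)) return(rep(FALSE, length(x)))
    m <- mean(x); s <- sd(x)
    if (s == 0) return(rep(FALSE, length(x)))
    abs(x - m) > n_sd * s
  }
  out_prd <- flag(metrics$prd)
  out_cc <- flag(metrics$cc)
  if (all(out_prd) || all(out_cc)) stop("outlier rule flagged every segment")
  structure(list(
    n_segments = nrow(metrics),
    n_prd_outliers = sum(out_prd), n_cc_outliers = sum(out_cc),
    prd_mean = mean(metrics$prd[!out_prd]), prd_sd = sd(metrics$prd[!out_prd]),
    cc_mean = mean(metrics$cc[!out_cc]), cc_sd = sd(metrics$cc[!out_cc])),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d segments\n", x$n_segments))
  cat(sprintf("  PRD: mean %.2f%% (SD %.2f), %d outliers excluded\n",
              x$prd_mean, x$prd_sd, x$n_prd_outliers))
  cat(sprintf("  CC : mean %.3f (SD %.3f), %d outliers excluded\n",
              x$cc_mean, x$cc_sd, x$n_cc_outliers))
  invisible(x)
}
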