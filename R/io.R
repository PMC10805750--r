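# Plain-text persistence: one record = a metadata CSV plus a two-column
# sample CSV; a segment store = a wide sample CSV plus a sidecar CSV of
# per-row labels.

#' Write a waveform record as a pair of CSV files
#'
#' Produces `<subject>_meta.csv` (subject, sampling rate, rhythm, and the
#' annotation intervals as `start:end:rhythm` triples) and
#' `<subject>_samples.csv` (columns `ecg`, `ppg`).
#'
#' @param record a [waveform_record()].
#' @param dir output directory (created if missing).
#' @return the two file paths, invisibly.
#' @export
write_record <- function(record, dir) {
  stopifnot(inherits(record, "waveform_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta_path <- file.path(dir, paste0(record$subject_id, "_meta.csv"))
  samp_path <- file.path(dir, paste0(record$subject_id, "_samples.csv"))
  ann <- paste(sprintf("%d:%d:%s", record$annotations$start,
                       record$annotations$end, record$annotations$rhythm),
               collapse = ";")
  write.csv(data.frame(subject_id = record$subject_id, fs = record$fs,
                       rhythm = record$rhythm_label, annotations = ann),
            meta_path, row.names = FALSE)
  df <- data.frame(ecg = record$ecg)
  if (!is.null(record$ppg)) df$ppg <- record$ppg
  write.csv(df, samp_path, row.names = FALSE)
  invisible(c(meta = meta_path, samples = samp_path))
}

#' Read a waveform record written by [write_record()]
#'
#' @param dir directory holding the file pair.
#' @param subject_id record identifier.
#' @return a [waveform_record()].
#' @export
read_record <- function(dir, subject_id) {
  meta <- read.csv(file.path(dir, paste0(subject_id, "_meta.csv")),
                   stringsAsFactors = FALSE)
  samp <- read.csv(file.path(dir, paste0(subject_id, "_samples.csv")))
  parts <- strsplit(strsplit(meta$annotations, ";")[[1]], ":")
  ann <- data.frame(start = as.integer(vapply(parts, `[`, "", 1)),
                    end = as.integer(vapply(parts, `[`, "", 2)),
                    rhythm = vapply(parts, `[`, "", 3))
  waveform_record(samp$ecg, if ("ppg" %in% names(samp)) samp$ppg else NULL,
                  meta$fs, meta$rhythm, meta$subject_id, ann)
}

#' Write a segment store as CSV
#'
#' `<prefix>_segments.csv` holds one segment per row (plus a paired
#' `<prefix>_ecg.csv` when present); `<prefix>_sidecar.csv` holds the
#' per-row label, origin and parent id along with the store geometry.
#'
#' @param store a [segment_store()].
#' @param prefix path prefix for the output files.
#' @return the file paths, invisibly.
#' @export
write_store <- function(store, prefix) {
  stopifnot(inherits(store, "segment_store"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  seg_path <- paste0(prefix, "_segments.csv")
  side_path <- paste0(prefix, "_sidecar.csv")
  utils::write.table(store$segments, seg_path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  paths <- c(segments = seg_path, sidecar = side_path)
  if (!is.null(store$ecg)) {
    ecg_path <- paste0(prefix, "_ecg.csv")
    utils::write.table(store$ecg, ecg_path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, ecg = ecg_path)
  }
  write.csv(data.frame(label = store$labels, origin = store$origin,
                       parent_id = store$parent_id, fs = store$fs,
                       segment_seconds = store$segment_seconds),
            side_path, row.names = FALSE)
  invisible(paths)
}

#' Read a segment store written by [write_store()]
#'
#' @param prefix path prefix used at write time.
#' @return a [segment_store()].
#' @export
read_store <- function(prefix) {
  segs <- as.matrix(read.csv(paste0(prefix, "_segments.csv"), header = FALSE))
  side <- read.csv(paste0(prefix, "_sidecar.csv"), stringsAsFactors = FALSE)
  ecg_path <- paste0(prefix, "_ecg.csv")
  ecg <- if (file.exists(ecg_path)) as.matrix(read.csv(ecg_path, header = FALSE)) else NULL
  dimnames(segs) <- NULL
  if (!is.null(ecg)) dimnames(ecg) <- NULL
  segment_store(segs, side$label, side$origin, side$parent_id,
                fs = side$fs[1], segment_seconds = side$segment_seconds[1],
                ecg = ecg)
}
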