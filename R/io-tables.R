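#' Write / read an HRV feature table as CSV
#'
#' Header names the 12 features (canonical order) plus `label` and
#' `source_id`. Values round-trip to at least 12 significant digits.
#' Reading matches columns by header name, so permuted columns read back
#' correctly; a missing feature column is a format error.
#'
#' @param features n x 12 numeric matrix.
#' @param labels Binary labels (1 = AF).
#' @param source_ids Segment identifiers.
#' @param path CSV path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a list with `features`, `labels`,
#'   `source_ids`.
#' @export
write_feature_table <- function(features, labels, source_ids, path) {
  features <- as.matrix(features)
  if (nrow(features)) {
    if (ncol(features) != 12L) stop("feature matrix must have 12 columns")
    stopifnot(nrow(features) == length(labels),
              nrow(features) == length(source_ids))
  }
  df <- as.data.frame(features)
  names(df) <- hrv_feature_names()
  df$label <- as.integer(labels)
  df$source_id <- as.character(source_ids)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = which(names(df) == "source_id"))
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(hrv_feature_names(), "label", "source_id")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("feature table format error: missing column(s) %s",
                 paste(missing, collapse = ", ")))
  }
  features <- as.matrix(df[, hrv_feature_names(), drop = FALSE])
  storage.mode(features) <- "double"
  list(features = features, labels = as.integer(df$label),
       source_ids = as.character(df$source_id))
}

#' Write / read a segment bundle
#'
#' A directory holding one CSV of samples per segment plus a JSON sidecar
#' with its metadata (fs, modality, label, source id, window index).
#'
#' @param segments List of [segment_record()]s.
#' @param dir Bundle directory (created if needed).
#' @return `write_segment_bundle` returns `dir` invisibly;
#'   `read_segment_bundle` returns the segment list.
#' @export
write_segment_bundle <- function(segments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    stem <- file.path(dir, sprintf("segment-%05d", i))
    utils::write.csv(data.frame(sample = seg$signal$samples),
                     paste0(stem, ".csv"), row.names = FALSE)
    jsonlite::write_json(
      list(fs = seg$signal$fs, modality = seg$signal$modality,
           t0_ms = seg$signal$t0_ms, label = seg$label,
           source_id = seg$source_id, window_index = seg$window_index),
      paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_segment_bundle
#' @export
read_segment_bundle <- function(dir) {
  metas <- sort(list.files(dir, pattern = "^segment-\\d+\\.json$",
                           full.names = TRUE))
  if (!length(metas)) stop(sprintf("no segments found in %s", dir))
  lapply(metas, function(mp) {
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    samples <- utils::read.csv(sub("\\.json$", ".csv", mp))$sample
    segment_record(af_signal(samples, meta$fs, meta$modality, meta$t0_ms),
                   label = meta$label, source_id = meta$source_id,
                   window_index = meta$window_index)
  })
}

#' Read a raw numeric sensor dump (one value per line or single CSV column)
#'
#' @param path CSV/plain-text file of samples.
#' @param fs Sampling rate in Hz.
#' @param modality `"ECG"` or `"PPG"`.
#' @return An [af_signal()].
#' @export
read_signal_csv <- function(path, fs, modality = "ECG") {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1L]][1L])))
  df <- utils::read.csv(path, header = has_header)
  af_signal(as.numeric(df[[1L]]), fs, modality)
}
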