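#' Labeled 30-s segment
#'
#' @param signal An [af_signal()] of exactly 30 s (`length == 30 * fs`).
#' @param label 0 = NSR, 1 = AF.
#' @param source_id Originating record identifier.
#' @param window_index 0-based index of the window within the record.
#' @return A `segment_record` list.
#' @export
segment_record <- function(signal, label, source_id = "", window_index = 0L) {
  stopifnot(inherits(signal, "af_signal"))
  if (length(signal$samples) != as.integer(round(30 * signal$fs))) {
    stop("segment must be exactly 30 s long at its sampling rate")
  }
  if (!label %in% c(0L, 1L)) stop("label must be 0 (NSR) or 1 (AF)")
  structure(list(signal = signal, label = as.integer(label),
                 source_id = source_id, window_index = as.integer(window_index)),
            class = "segment_record")
}

#' Window labeling rules
#'
#' The beat-saturation rule: a window not already rhythm-labeled AF, whose
#' beats all belong to the N (N, L, R, B) or S (A, a, J, S, j, e, n)
#' superclasses, is relabeled AF when the S fraction strictly exceeds the
#' threshold ("over 50%"); windows with zero S beats are left to their
#' rhythm label.
#'
#' @param s_saturation_threshold S-beat fraction above which a window
#'   becomes AF (strict inequality).
#' @param s_beat_alphabet,n_beat_alphabet Beat symbol superclasses
#'   (disjoint).
#' @param min_peaks_per_window Minimum detected peaks for a window to enter
#'   the feature dataset (5 peaks = 4 intervals, the feature minimum).
#' @return A `label_rule_config` list.
#' @export
label_rule_config <- function(s_saturation_threshold = 0.5,
                              s_beat_alphabet = c("A", "a", "J", "S", "j", "e", "n"),
                              n_beat_alphabet = c("N", "L", "R", "B"),
                              min_peaks_per_window = 5L) {
  if (s_saturation_threshold <= 0 || s_saturation_threshold > 1) {
    stop("threshold must be in (0, 1]")
  }
  if (length(intersect(s_beat_alphabet, n_beat_alphabet))) {
    stop("beat alphabets must be disjoint")
  }
  structure(list(s_saturation_threshold = s_saturation_threshold,
                 s_beat_alphabet = s_beat_alphabet,
                 n_beat_alphabet = n_beat_alphabet,
                 min_peaks_per_window = as.integer(min_peaks_per_window)),
            class = "label_rule_config")
}

#' Cut an annotated record into labeled 30-s windows
#'
#' Consecutive non-overlapping 30-s windows from the record start. A window
#' fully inside a single NSR or AF rhythm interval takes that label; windows
#' overlapping an excluded (OTHER) rhythm, or straddling a rhythm boundary,
#' are dropped, as is the trailing partial window. Windows not rhythm-labeled
#' AF are re-examined under the beat-saturation rule (see
#' [label_rule_config()]); a window with no rhythm label that saturates is
#' labeled AF, otherwise it is dropped.
#'
#' @param signal An [af_signal()] for the whole record.
#' @param rhythms A [rhythm_intervals()] (may be empty).
#' @param beats A [beat_annotations()] (may be empty).
#' @param rules A [label_rule_config()].
#' @return List of [segment_record()]s (possibly empty).
#' @export
segment_windows <- function(signal, rhythms = rhythm_intervals(),
                            beats = beat_annotations(),
                            rules = label_rule_config()) {
  stopifnot(inherits(signal, "af_signal"))
  win_ms <- 30000
  spw <- as.integer(round(30 * signal$fs))
  n_win <- length(signal$samples) %/% spw
  out <- list()
  for (k in seq_len(n_win) - 1L) {
    ws <- signal$t0_ms + k * win_ms
    we <- ws + win_ms

    lab <- NA_character_
    if (nrow(rhythms)) {
      ov <- rhythms$start_ms < we & rhythms$end_ms > ws
      if (any(ov)) {
        if (any(rhythms$rhythm[ov] == "OTHER")) next       # excluded rhythm
        covering <- ov & rhythms$start_ms <= ws & rhythms$end_ms >= we
        if (!any(covering)) next                           # straddles a boundary
        lab <- rhythms$rhythm[which(covering)[1L]]
      }
    }

    if (is.na(lab) || lab != "AF") {
      inw <- beats$times_ms >= ws & beats$times_ms < we
      bl <- beats$labels[inw]
      if (length(bl) &&
          all(bl %in% c(rules$n_beat_alphabet, rules$s_beat_alphabet))) {
        n_s <- sum(bl %in% rules$s_beat_alphabet)
        if (n_s > 0L && n_s / length(bl) > rules$s_saturation_threshold) {
          lab <- "AF"
        }
      }
    }
    if (is.na(lab)) next

    i0 <- k * spw + 1L
    seg_sig <- af_signal(signal$samples[i0:(i0 + spw - 1L)], signal$fs,
                         signal$modality, t0_ms = ws)
    out[[length(out) + 1L]] <- segment_record(
      seg_sig, label = as.integer(lab == "AF"),
      source_id = "", window_index = k)
  }
  out
}

#' Build the feature/label matrix from labeled segments
#'
#' Runs each segment through the detection chain (optional bandpass filter
#' and resampling to the working rate, peak detection, interval conversion,
#' the 12 HRV features). Segments yielding fewer than
#' `rules$min_peaks_per_window` peaks are dropped and reported.
#'
#' @param segments List of [segment_record()]s.
#' @param config A [pipeline_config()].
#' @param preprocess Apply the modality bandpass filter and resample to the
#'   working rate first (set `FALSE` if segments are already preprocessed).
#' @return List: `features` (n x 12 matrix), `labels`, `kept_ids`,
#'   `dropped` (data.frame of dropped segment ids and reasons).
#' @export
build_feature_dataset <- function(segments, config = pipeline_config(),
                                  preprocess = TRUE) {
  if (!length(segments)) stop("no segments supplied")
  rules <- config$label_rules
  rows <- list()
  labs <- integer(0)
  kept <- character(0)
  dropped <- data.frame(segment_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (seg in segments) {
    sig <- seg$signal
    if (preprocess) {
      sig <- bandpass_filter(sig, config$filters[[sig$modality]])
      if (sig$fs != config$working_fs) {
        sig <- resample_fft(sig, config$working_fs)
      }
    }
    pk <- detect_peaks(sig, config$peak_configs[[sig$modality]])
    id <- if (nzchar(seg$source_id)) seg$source_id
          else sprintf("window-%d", seg$window_index)
    if (length(pk$indices) < rules$min_peaks_per_window) {
      dropped <- rbind(dropped, data.frame(
        segment_id = id, reason = sprintf("only %d peaks", length(pk$indices)),
        stringsAsFactors = FALSE))
      next
    }
    feats <- compute_features(peaks_to_rr(pk),
                              prr_denominator = config$prr_denominator)
    rows[[length(rows) + 1L]] <- feats
    labs <- c(labs, seg$label)
    kept <- c(kept, id)
  }
  if (!length(rows)) stop("all segments were dropped; empty dataset")
  features <- do.call(rbind, rows)
  rownames(features) <- NULL
  list(features = features, labels = labs, kept_ids = kept, dropped = dropped)
}
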