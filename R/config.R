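#' Full pipeline configuration
#'
#' Bundles the working rate, per-modality filter and peak-detector settings,
#' window labeling rules, training protocol and master seed. Defaults are
#' the published values wherever one exists (working rate 50 Hz, ECG
#' bandpass order 2 at 8-20 Hz, PPG order 3 at 0.5-8 Hz, detector windows
#' 100/525 ms ECG and 111/667 ms PPG, batch 16, 50 epochs, Adam, 5-fold CV).
#'
#' @param working_fs Common working sampling rate (Hz).
#' @param ecg_filter,ppg_filter [filter_spec()]s per modality.
#' @param ecg_peaks,ppg_peaks [peak_detect_config()]s per modality.
#' @param label_rules A [label_rule_config()].
#' @param train A [train_config()].
#' @param prr_denominator `"n"` or `"n-1"` (see [compute_features()]).
#' @param af_aux_strings WFDB rhythm aux strings counted as AF.
#' @param nsr_record_fraction,nsr_afdb_fraction Seeded record/segment
#'   subsampling fractions for NSR material (protocol knobs; 1 = keep all).
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(working_fs = 50,
                            ecg_filter = default_filter_spec("ECG"),
                            ppg_filter = default_filter_spec("PPG"),
                            ecg_peaks = peak_detect_config("ECG"),
                            ppg_peaks = peak_detect_config("PPG"),
                            label_rules = label_rule_config(),
                            train = train_config(),
                            prr_denominator = "n",
                            af_aux_strings = "(AFIB",
                            nsr_record_fraction = 0.15,
                            nsr_afdb_fraction = 0.05,
                            seed = 1L) {
  structure(list(working_fs = working_fs,
                 filters = list(ECG = ecg_filter, PPG = ppg_filter),
                 peak_configs = list(ECG = ecg_peaks, PPG = ppg_peaks),
                 label_rules = label_rules, train = train,
                 prr_denominator = prr_denominator,
                 af_aux_strings = af_aux_strings,
                 nsr_record_fraction = nsr_record_fraction,
                 nsr_afdb_fraction = nsr_afdb_fraction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' Round-trips losslessly: `read_pipeline_config(write_pipeline_config(x))`
#' reproduces every field.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("working_fs", "filters", "peak_configs", "label_rules", "train",
           "prr_denominator", "seed")
  missing <- setdiff(req, names(j))
  if (length(missing)) {
    stop(sprintf("config validation failed: missing field(s) %s",
                 paste(missing, collapse = ", ")))
  }
  fs_from <- function(f) filter_spec(f$order, f$low_hz, f$high_hz)
  pc_from <- function(p) peak_detect_config(p$modality, p$w1_ms, p$w2_ms,
                                            p$beta_ms, p$squaring,
                                            p$clip_negatives)
  lr <- j$label_rules
  tc <- j$train
  pipeline_config(
    working_fs = j$working_fs,
    ecg_filter = fs_from(j$filters$ECG), ppg_filter = fs_from(j$filters$PPG),
    ecg_peaks = pc_from(j$peak_configs$ECG),
    ppg_peaks = pc_from(j$peak_configs$PPG),
    label_rules = label_rule_config(lr$s_saturation_threshold,
                                    lr$s_beat_alphabet, lr$n_beat_alphabet,
                                    lr$min_peaks_per_window),
    train = train_config(tc$batch_size, tc$epochs, tc$lr, tc$cv_folds,
                         tc$train_frac, tc$seed, tc$global_norm,
                         tc$threshold, as.list(tc$finetune)),
    prr_denominator = j$prr_denominator,
    af_aux_strings = unlist(j$af_aux_strings),
    nsr_record_fraction = j$nsr_record_fraction %||% 0.15,
    nsr_afdb_fraction = j$nsr_afdb_fraction %||% 0.05,
    seed = j$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
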