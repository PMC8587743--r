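#!/usr/bin/env Rscript
# Optional protocol reproduction on locally supplied MIT-BIH WFDB records.
#
# The headline ambulatory-ECG results cannot be reproduced without the
# PhysioNet databases (NSR-DB, AF-DB, ARR-DB) and the original study's
# unspecified arbitrary record selection; the wearable PPG database
# (UMass-DB) is access-restricted. This script therefore runs the full ECG
# protocol -- 30-s windowing with rhythm/saturation labeling, filtering,
# resampling to 50 Hz, peak detection, HRV features, stratified 5-fold CNN
# training -- against WFDB records *you* place under a local directory. It
# is not part of the package's acceptance checks.
#
# usage: Rscript scripts/reproduce_mitbih.R --records <dir> [--seed 1]
#   <dir> must contain WFDB header/data/annotation triples
#   (record.hea / record.dat / record.atr, format 16).

suppressPackageStartupMessages({
  library(optparse)
  library(pulseaf)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--records", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results/mitbih.json")
)))

if (is.null(opts$records) || !dir.exists(opts$records)) {
  message("No local WFDB record directory supplied (--records <dir>).")
  message("Download the MIT-BIH databases from PhysioNet and convert to")
  message("format 16 first; this reproduction cannot run without them.")
  quit(save = "no", status = 3)
}

headers <- list.files(opts$records, pattern = "\\.hea$", full.names = TRUE)
if (!length(headers)) {
  message("No .hea files found under ", opts$records)
  quit(save = "no", status = 3)
}

cfg <- pipeline_config(seed = opts$seed)
segments <- list()
for (hea in headers) {
  base <- sub("\\.hea$", "", hea)
  sig <- read_wfdb_record(base, channel = 0, modality = "ECG")
  atr <- paste0(base, ".atr")
  ann <- if (file.exists(atr)) {
    read_wfdb_annotations(atr, fs = sig$fs,
                          record_end_ms = 1000 * length(sig$samples) / sig$fs,
                          af_aux_strings = cfg$af_aux_strings)
  } else list(beats = beat_annotations(), rhythms = rhythm_intervals())
  segs <- segment_windows(sig, ann$rhythms, ann$beats, cfg$label_rules)
  for (i in seq_along(segs)) segs[[i]]$source_id <-
      sprintf("%s-w%04d", basename(base), segs[[i]]$window_index)
  segments <- c(segments, segs)
}
message(sprintf("collected %d labeled 30-s windows from %d records",
                length(segments), length(headers)))

labels <- vapply(segments, function(s) s$label, integer(1))
# seeded record-level NSR subsampling, as in the original protocol
if (cfg$nsr_record_fraction < 1) {
  set.seed(opts$seed)
  nsr_idx <- which(labels == 0L)
  keep <- sort(sample(nsr_idx, ceiling(cfg$nsr_record_fraction *
                                         length(nsr_idx))))
  segments <- c(segments[keep], segments[labels == 1L])
}

ds <- build_feature_dataset(segments, cfg)
fit <- train_cv(ds$features, ds$labels, cfg$train)
print(fit)

dir.create(dirname(opts$out), showWarnings = FALSE, recursive = TRUE)
jsonlite::write_json(
  list(n_segments = length(ds$labels),
       holdout = unclass(fit$holdout)[c("accuracy", "sensitivity",
                                        "specificity", "f1", "auc")],
       cv = fit$cv_summary),
  opts$out, auto_unbox = TRUE, digits = NA)
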