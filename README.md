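# pulseaf

Cross-modality atrial fibrillation (AF) screening from short rhythm
strips, for researchers working with ambulatory ECG archives and wearable
PPG sensors. A 30-s single-channel strip is bandpass-filtered, resampled
to a 50 Hz working rate, beat-detected with a two event-related
moving-average block detector, reduced to twelve time-domain
heart-rate-variability (HRV) features, and classified NSR-vs-AF by a
compact 1-D convolutional network. Because the classifier consumes HRV
statistics rather than raw morphology, an ECG-trained network transfers
to PPG-derived pulse-rate variability by finetuning.

## The method in brief

Beat detection: with a filtered strip S[n], two centred moving averages
are compared — MA_peak (window W1, the expected peak duration: 100 ms for
a QRS complex, 111 ms for a PPG systolic peak) and MA_beat (window W2,
the expected beat duration: 525/667 ms). Runs where MA_peak > MA_beat are
blocks of interest; blocks narrower than α = W1 + β samples are rejected,
and each surviving block contributes one peak at the argmax of the
filtered signal. The PPG variant squares the clipped signal first to
suppress the diastolic wave and dicrotic notch.

From the inter-beat intervals RR_1..RR_N (ms), the features include

    rMSSD = sqrt( Σ_{i=1}^{N-1} (RR_i − RR_{i+1})² / (N − 1) )
    SDRR  = sqrt( Σ_j (RR_j − mean(RR))² / (N − 1) )

plus meanRR, medianRR, madRR, mcvRR, CVRR = SDRR/meanRR,
CVSD = rMSSD/meanRR, and the threshold counts RR20/RR50 with their
proportions pRR20/pRR50 (successive differences strictly exceeding
20/50 ms). AF elevates rMSSD, pRR50 and the coefficients of variation —
that separation is what the network learns.

The classifier is four Conv1D layers (256/128/64/32 filters, kernel 3,
ReLU, batch-normalised), dropout 0.2, max-pool 2, then dense 8 (ReLU) and
a single sigmoid output; trained with Adam, mini-batch 16, 50 epochs,
stratified 5-fold cross-validation inside a stratified 80/20 split.
Evaluation reports accuracy, sensitivity, specificity, F1 (positive
class = AF) and rank-based AUC. Transfer to PPG retrains all layers at a
reduced learning rate under a stratified 4-fold 75/25 scheme.

The package also ships a minimal WFDB reader/writer (text headers,
format-16 signals, MIT-format annotations), CSV feature tables, a seeded
physiological signal simulator with ground-truth beat times, and a
command-line front-end (`inst/cli/pulseaf.R`).

## Worked example

```r
library(pulseaf)

# a labeled synthetic corpus: 40 NSR + 40 AF 30-s ECG strips at 128 Hz
corp <- gen_corpus(40, 40, seed = 17)
ds   <- build_feature_dataset(corp$segments, pipeline_config())
fit  <- train_cv(ds$features, ds$labels, train_config(epochs = 15, seed = 17))
fit
#> <af_cnn_fit> NSR-vs-AF classifier
#> cross-validation (mean +/- sd over folds):
#>   accuracy     100.00 +/- 0.00
#>   sensitivity  100.00 +/- 0.00
#>   specificity  100.00 +/- 0.00
#>   f1           100.00 +/- 0.00
#>   auc          100.00 +/- 0.00
#> holdout: accuracy 100.00%  sensitivity 100.00%  specificity 100.00%  F1 100.00%  AUC 100.00%

# classify a fresh 35-s AF strip end to end
rr    <- gen_rr_series(rr_model("AF"), 70, seed = 902)
strip <- gen_waveform(rr, fs = 128, modality = "ECG",
                      duration_ms = 35000, start_ms = 400)
run_end_to_end(strip$signal, fit)
#>           id probability label
#> 1 window-000   0.9943508     1
```

One full 30-s window is scored (the 5-s tail is dropped); the probability
is the sigmoid output for AF and `label` applies the 0.5 threshold. On a
clean synthetic corpus the classes separate completely — see the methods
vignette (`vignettes/methods.Rmd`) for what that does and does not say
about real recordings.

For real data, point `read_wfdb_record()` / `read_wfdb_annotations()` at
WFDB header/data/annotation triples, cut windows with
`segment_windows()`, and proceed identically.

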