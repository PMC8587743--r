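Package: pulseaf
Title: Atrial Fibrillation Screening from Short ECG and PPG Rhythm Strips
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-modality atrial fibrillation (AF) screening pipeline for
    short (30 s) single-channel ECG and PPG rhythm strips. Signals are
    bandpass-filtered with zero-phase Butterworth designs, resampled to a
    common working rate by Fourier-domain resampling, and beat-detected with
    a two event-related moving-average block detector (R peaks on ECG,
    systolic peaks on PPG). Detected inter-beat intervals are reduced to
    twelve time-domain heart-rate-variability features which feed a compact
    one-dimensional convolutional network classifying normal sinus rhythm
    versus AF, trained with stratified cross-validation and adapted from ECG
    to PPG by finetuning. Includes a minimal WFDB record/annotation
    reader-writer, a seeded physiological signal simulator with ground-truth
    beat times for validation, and a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
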