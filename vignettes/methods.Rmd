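---
title: "Methods: cross-modality atrial fibrillation screening from 30-s rhythm strips"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-modality atrial fibrillation screening from 30-s rhythm strips}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulseaf)
```

## The problem and the pipeline

Atrial fibrillation (AF) is defined by irregular, weakly correlated
beat-to-beat intervals. That signature survives the change of sensor: it is
visible both in the R-R intervals of a single-lead ECG and in the
systolic-peak-to-systolic-peak intervals of a wrist PPG. `pulseaf`
implements a screening pipeline that exploits exactly this: a short (30 s)
strip is reduced to twelve time-domain heart-rate-variability (HRV)
statistics, and a compact 1-D convolutional network classifies the vector
as normal sinus rhythm (NSR) or AF. Because the features, not the raw
morphology, carry the decision, a network trained on ECG-derived HRV can be
adapted to PPG-derived pulse-rate variability (PRV) by finetuning alone.

The stages, each its own module:

1. **Preprocessing** — modality-specific Butterworth bandpass
   (ECG: order 2, 8–20 Hz; PPG: order 3, 0.5–8 Hz), Fourier-domain
   resampling to a common 50 Hz working rate.
2. **Peak detection** — two event-related moving averages with block
   generation and a width threshold (R peaks on ECG, systolic peaks on
   PPG).
3. **Feature extraction** — the 12 time-domain HRV/PRV statistics.
4. **Dataset construction** — 30-s non-overlapping windows labeled from
   rhythm annotations and a supraventricular-beat saturation rule.
5. **Classification** — a small 1-D CNN trained with stratified 5-fold
   cross-validation inside a stratified 80/20 split, and a 4-fold
   finetuning scheme for ECG-to-PPG transfer.
6. **Synthesis** — a seeded generator of RR processes, ECG/PPG-like
   waveforms and labeled corpora with ground-truth beat times, used as the
   test bed for every other module.

## Preprocessing choices

**Zero-phase filtering.** The Butterworth design is applied
forward-backward. The filter exists to serve *timing* (peak positions feed
the HRV statistics), so phase distortion is the one error we cannot
afford; zero-phase filtering removes it at the cost of doubling the
effective order. The signal is extended by odd reflection before filtering
and trimmed afterwards, which suppresses the edge transients a plain
forward-backward pass produces. Filtering precedes resampling; with a
20 Hz upper edge against a 25 Hz working Nyquist the order is
mathematically immaterial, so the narrative order of the protocol is kept.

**Fourier resampling.** Downsampling to `round(n * 50 / fs)` samples is
done by spectrum truncation (with the shared Nyquist bin folded when the
source length is even), so band-limited content below 25 Hz passes
through unchanged. 50 Hz is the default working rate — the minimum at
which short-term HRV parameters remain accurate, and a rate every
consumer PPG sensor can deliver — exposed as `working_fs` in
`pipeline_config()`.

**Normalisation.** Features are z-scored with the sample (n−1) standard
deviation. Statistics are fit on the training partition only and stored
with the model; fitting them globally leaks information from the holdout
set into training, so the global variant is available but opt-in
(`global_norm = TRUE`).

## The peak detector

The detector computes two centred moving averages of the clipped
(and, for PPG, squared) filtered signal: a *peak-scale* average with
window `W1` (ECG 100 ms, the duration of a QRS complex; PPG 111 ms, a
systolic upstroke) and a *beat-scale* average with window `W2` (ECG
525 ms; PPG 667 ms). Runs of samples where the peak-scale average
strictly exceeds the beat-scale average are *blocks of interest*; blocks
narrower than `W1 + beta` samples are rejected as noise, and each
surviving block contributes one peak at the argmax of the filtered signal
(earliest index on ties, so results are deterministic). Squaring is applied
only in the PPG variant, where it suppresses the diastolic bump and
dicrotic notch relative to the systolic peak.

Decisions where the published description is silent:

* **Centred vs trailing windows** — centred. A trailing average would
  shift block onsets by up to `W1/2`; centring keeps the block symmetric
  around the peak.
* **Edge policy** — reflection padding. A zero-padded onset would
  depress the beat-scale average at the record ends and create spurious
  onset blocks.
* **Negative clipping** — applied in both variants before averaging, so
  the negative lobes of a bandpassed QRS cannot suppress the peak-scale
  average.
* **The lower bound `TH1`** mentioned alongside the window definitions is
  never given a formula in the source description; thresholding is
  implemented exactly as the pseudocode (width-only rejection) and `TH1`
  is unused.
* `beta` defaults to 0 and `alpha` is measured in samples after the
  ms-to-sample conversion (windows forced odd).

A beat whose template support is cut by the strip boundary (a beat in the
first or last ~200 ms) can lose its block to the width threshold or have
its apex displaced by the reflection padding; recovery guarantees
therefore apply to beats with full support, and the corpus generator
starts beat trains at a random phase offset inside the first interval, as
in real recordings where window boundaries do not align with beats.

## The twelve features

In fixed order: meanRR, medianRR, madRR, mcvRR, SDRR, rMSSD, CVRR, CVSD,
RR20, pRR20, RR50, pRR50. Conventions that needed fixing:

* rMSSD is `sqrt( sum (RR_i − RR_{i+1})^2 / (N − 1) )` — the square root
  is applied (the printed formula omits the radical, but the feature *is*
  a root mean square and is described as such).
* SDRR uses the sample (n−1) denominator.
* RR20/RR50 count successive differences *strictly* greater than
  20/50 ms ("differing by more than").
* pRR20/pRR50 divide by N, the total number of intervals, following the
  stated wording; the conventional pNN-style N−1 denominator is available
  via `prr_denominator = "n-1"`.
* CVSD is rMSSD/meanRR; madRR is the raw median absolute deviation about
  the median (no 1.4826 consistency factor); mcvRR is madRR/medianRR. None
  of the three is given a formula in the source, so the standard
  definitions are used.
* A window must yield at least 4 intervals (5 peaks); the stated minimum
  beat count per window (4) cannot support the successive-difference
  features, so the effective minimum is 5 peaks.

The NSR generator defaults reproduce the normative short-term reference
statistics (mean RR 926 ± 90 ms); with the AR(1) correlation of 0.7 the
implied rMSSD is `90 * sqrt(2 * (1 − 0.7)) ≈ 70` ms, inside the 19–75 ms
reference band, which is precisely why 0.7 was chosen.

## Dataset construction

Windows are half-open intervals `[k·30 s, (k+1)·30 s)` from the record
start; the trailing partial window is discarded. A window wholly
inside one NSR or AF rhythm interval takes that label. Windows overlapping
an excluded rhythm (paced, bigeminy, trigeminy, tachycardia and anything
else mapped to OTHER) are dropped, and — a case the source never defines —
windows straddling a rhythm boundary are dropped too, because a mixed
window has no honest label. Windows not rhythm-labeled AF are re-examined
against their beat annotations: if every beat belongs to the N (N, L, R,
B) or S (A, a, J, S, j, e, n) superclasses and the S fraction strictly
exceeds 50%, the window is treated as AF ("over 50%" read literally, so
exactly half does not qualify); with zero S beats the rule is skipped.
Saturation never overrides an AF rhythm label, and is the only way an
unannotated window can enter the dataset.

## The classifier

The network is fixed: four Conv1D layers (256, 128, 64, 32 filters,
kernel 3, stride 1, ReLU), each followed by batch normalisation, then
dropout 0.2, max-pooling 2, flatten, a dense ReLU layer of 8 units and a
single sigmoid output; input is the 12-feature vector as a length-12,
one-channel sequence. Points where the description conflicts with itself
or is silent:

* Kernel size is 3 (the tabulated value); the prose mention of "5 × 5"
  filters is two-dimensional and inconsistent with the table, so the table
  wins.
* Padding is unspecified; `same` (length-preserving) padding is used, so
  shapes run 12 → 12 → 12 → 12 → 12 → pool → 6 → flatten 192 → 8 → 1.
  With `valid` padding the sequence would shrink to 4 before pooling,
  making the architecture fragile to any input-length change.
* The loss is never named; binary cross-entropy is forced by the
  single-sigmoid output.
* Adam uses the framework-default hyperparameters (lr 1e-3, β₁ 0.9,
  β₂ 0.999); the decision threshold is 0.5; the positive class is AF
  throughout (the evaluation prose defines TP/FP/FN/TN for AF even though
  the metric equations are typeset with NSR subscripts).

The engine is implemented directly in R on BLAS matrix products:
activations are stored position-major so the kernel-3 convolution is a
single matrix multiply against a block-shifted design matrix, and
batch-norm/dropout/max-pool backward passes follow the standard formulas.
Backpropagation is verified against central-difference numerical gradients
in the test suite. Batch normalisation uses momentum 0.99 and ε = 1e-3 for
the running statistics; batches of size 1 are skipped (batch statistics
are undefined there).

**Protocol.** Stratified 80/20 outer split; stratified 5-fold CV inside
the 80% (each fold a fresh network, mini-batch 16, 50 epochs); a final
model refit on the full 80% and scored once on the 20% holdout. Every
random choice (splits, fold assignment, weight init, batch shuffling,
dropout) derives from the config seed, so a fit is bit-reproducible.

**Transfer.** Finetuning retrains *all* layers (nothing frozen) at
lr × 0.1 under a stratified 4-fold scheme over a 75/25 split, so every
target-modality instance is scored exactly once by weights that never saw
it; the reported transfer metrics are the fold aggregate. Normalisation is
refit on each fold's training portion by default — the target modality has
its own feature scale — with `reuse_stats = TRUE` to force the source
stats. The learning-rate reduction is this package's addition (the source
only says the weights are "updated by retraining") and is flag-controlled.

## The synthetic test bed

`gen_rr_series()` draws NSR as a stationary AR(1) Gaussian process
(mean 926 ms, sd 90 ms, ρ = 0.7, floored at 400 ms) and AF as i.i.d.
normal draws (mean 700 ms, sd 180 ms, floored at 300 ms) with a 0.2-weight
uniform(350, 1400) jump component. No AF RR distribution is published in
the source material; the AF parameterisation is this package's own
scaffolding, designed to produce the defining phenotype (high variance, no
autocorrelation, occasional extreme intervals) and frozen.

`gen_waveform()` renders beats as Gaussian templates: ECG as a unit
QRS bump (σ = 20 ms, optional P/T bumps), PPG as a systolic/diastolic
double pulse (σ 60 ms amplitude 1; σ 90 ms amplitude 0.4 delayed 250 ms).
Optional noise: white Gaussian at a stated SNR, 0.3 Hz baseline wander,
powerline (injected at the native pre-resampling rate so the filter chain
is exercised realistically), and short motion bursts. Ground-truth peak
times are returned with every render.

What the generator does *not* emulate: realistic QRS/P/T morphology
variation, ectopic beat morphology, PPG amplitude modulation with
respiration, sensor saturation, or non-stationary noise. Passing the
recovery tests therefore shows the algorithmic chain is correct under the
stated signal model, not that clinical-grade performance transfers to
arbitrary real recordings.

**The transfer cohort** (`gen_transfer_corpus()`) defines the
transfer-learning study: 96 NSR + 48 AF PPG segments (the 2:1 imbalance of
a screening cohort) with per-beat pulse-arrival-time jitter (sd 40 ms, the
variable pulse-transit delay of optical sensing, which inflates NSR PRV)
and a markedly milder AF arm (mean 850 ms, sd 85 ms, jump weight 0.03 — a
rate-controlled/paroxysmal presentation) than the ambulatory ECG defaults.
The construction goal is a genuine covariate shift: the un-adapted
ECG-trained network must sit on the wrong side of its learned boundary for
a substantial part of the mild-AF class while the two classes remain
separable *within* the new domain, so that finetuning has both room and
information to improve. These parameters are fixed conditions of the
study, not tuning knobs.

## Problem sizes and numerical choices

The packaged experiments run at desk scale, chosen once: 200 + 200 ECG
segments for training (about 115 s of CPU for the full CV protocol),
96 + 48 PPG segments per transfer cohort over 5 seeds, 30-s strips at a
128 Hz native render rate, and 100-seed Monte-Carlo batches for detector
robustness. Tolerances worth knowing: the 50 Hz working rate quantises
peak times to 20 ms, which bounds the relative error of successive-
difference features on short AF intervals (the end-to-end tests allow a
15% worst case with a 5% median for rMSSD/SDRR on clean strips);
moving-average windows are forced odd; constant feature columns get unit
sd with a warning; undefined metrics (zero denominators, one-class AUC)
return `NA` with a warning rather than failing.

## Known limitations

* The WFDB support is a minimal dialect: text headers, format-16 signals,
  MIT-format annotations with beat codes, rhythm markers and aux strings.
  It round-trips its own output and reads the subset of PhysioBank
  conventions the pipeline needs, nothing more.
* The headline ambulatory-ECG/PPG results of the original study are not
  reproducible from this package alone: they require PhysioNet downloads,
  an unspecified arbitrary record selection, and an access-restricted
  wearable database. `scripts/reproduce_mitbih.R` runs the full ECG
  protocol when records are supplied locally.
* Segment-level splitting matches the original protocol but allows
  windows of one patient on both sides of a split; no patient-level
  grouping is implemented.
* Frequency-domain and non-linear HRV measures are out of scope.

## A worked example

```{r example, eval = FALSE}
corp <- gen_corpus(40, 40, seed = 17)
ds <- build_feature_dataset(corp$segments, pipeline_config())
fit <- train_cv(ds$features, ds$labels, train_config(epochs = 15, seed = 17))
fit

rr <- gen_rr_series(rr_model("AF"), 70, seed = 902)
strip <- gen_waveform(rr, fs = 128, modality = "ECG",
                      duration_ms = 35000, start_ms = 400)
run_end_to_end(strip$signal, fit)
```
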