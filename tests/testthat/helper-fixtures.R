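# Shared fixture builders: everything is generated in code at test time.

# Greedy one-to-one matching of detected peaks to truth indices within a
# sample tolerance; returns recall and precision.
match_peaks <- function(detected_idx, truth_idx, tol_samples) {
  used <- logical(length(detected_idx))
  hits <- 0L
  for (t in truth_idx) {
    d <- abs(detected_idx - t)
    j <- which(d <= tol_samples & !used)
    if (length(j)) {
      used[j[which.min(d[j])]] <- TRUE
      hits <- hits + 1L
    }
  }
  c(recall = if (length(truth_idx)) hits / length(truth_idx) else NA_real_,
    precision = if (length(detected_idx)) sum(used) / length(detected_idx)
                else NA_real_)
}

# A constant-rate beat train whose beats all have full template support
# inside a 30-s window (first beat 400 ms in, last >= 500 ms before the
# end); returns the rendered waveform plus truth.
steady_train <- function(bpm, fs = 50, modality = "ECG", snr_db = NULL,
                         seed = NULL) {
  rr_ms <- 60000 / bpm
  n_beats <- floor((29500 - 400) / rr_ms) + 1
  wf_model <- waveform_model(snr_db = snr_db)
  gen_waveform(rep(rr_ms, n_beats - 1), wf_model, fs = fs,
               modality = modality, duration_ms = 30000, start_ms = 400,
               seed = seed)
}

# Independent naive-loop implementations of the HRV formulas, used as
# oracles against the package versions.
naive_rmssd <- function(x) {
  n <- length(x)
  acc <- 0
  for (i in 1:(n - 1)) acc <- acc + (x[i] - x[i + 1])^2
  sqrt(acc / (n - 1))
}
naive_sdrr <- function(x) {
  m <- sum(x) / length(x)
  acc <- 0
  for (v in x) acc <- acc + (v - m)^2
  sqrt(acc / (length(x) - 1))
}
naive_madrr <- function(x) {
  med <- sort(x)[ceiling(length(x) / 2)]
  if (length(x) %% 2 == 0) {
    s <- sort(x)
    med <- (s[length(x) / 2] + s[length(x) / 2 + 1]) / 2
  }
  dev <- abs(x - med)
  s <- sort(dev)
  if (length(dev) %% 2 == 1) s[ceiling(length(dev) / 2)]
  else (s[length(dev) / 2] + s[length(dev) / 2 + 1]) / 2
}
naive_prr <- function(x, thresh_ms, denom_n) {
  cnt <- 0L
  for (i in 1:(length(x) - 1)) {
    if (abs(x[i + 1] - x[i]) > thresh_ms) cnt <- cnt + 1L
  }
  c(count = cnt, prop = cnt / denom_n)
}

# Brute-force AUC over all positive-negative pairs (ties get half credit).
naive_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  acc <- 0
  for (p in pos) for (q in neg) {
    acc <- acc + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  acc / (length(pos) * length(neg))
}
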