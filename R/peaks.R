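#' Peak-detector configuration
#'
#' Parameters of the two event-related moving-average block detector. `w1_ms`
#' is the expected peak duration (QRS complex on ECG, systolic upstroke on
#' PPG) and sets the short moving-average window; `w2_ms` is the expected
#' full-beat duration and sets the long window. A candidate block — a run
#' where the short average exceeds the long one — is rejected when narrower
#' than `alpha = W1 + beta` samples. Squaring emphasises the systolic peak
#' over the diastolic peak and dicrotic notch and is used for PPG only.
#'
#' @param modality `"ECG"` or `"PPG"`; selects the published window defaults
#'   (ECG: 100/525 ms, PPG: 111/667 ms) and the squaring flag.
#' @param w1_ms,w2_ms Moving-average window durations (ms), `0 < w1 < w2`.
#' @param beta_ms Width-threshold offset in ms (may be negative, >= -w1_ms).
#' @param squaring Square the (clipped) signal before averaging.
#' @param clip_negatives Clip negative samples to zero before averaging.
#' @return A `peak_detect_config` list.
#' @export
peak_detect_config <- function(modality = c("ECG", "PPG"),
                               w1_ms = NULL, w2_ms = NULL, beta_ms = 0,
                               squaring = NULL, clip_negatives = TRUE) {
  modality <- match.arg(toupper(modality), c("ECG", "PPG"))
  if (is.null(w1_ms)) w1_ms <- if (modality == "ECG") 100 else 111
  if (is.null(w2_ms)) w2_ms <- if (modality == "ECG") 525 else 667
  if (is.null(squaring)) squaring <- modality == "PPG"
  if (!(w1_ms > 0 && w1_ms < w2_ms)) stop("need 0 < w1_ms < w2_ms")
  if (beta_ms < -w1_ms) stop("beta_ms must be >= -w1_ms")
  structure(list(modality = modality, w1_ms = w1_ms, w2_ms = w2_ms,
                 beta_ms = beta_ms, squaring = isTRUE(squaring),
                 clip_negatives = isTRUE(clip_negatives)),
            class = "peak_detect_config")
}

#' Centred moving average with reflection padding
#'
#' Mean over a centred odd-length window; edges are handled by reflecting
#' the sequence, so the output has the input's length. An even window is
#' widened by one sample with a warning.
#'
#' @param x Numeric vector.
#' @param window_samples Window length in samples (odd; must be <= length(x)).
#' @return Numeric vector, same length as `x`.
#' @export
moving_average <- function(x, window_samples) {
  n <- length(x)
  w <- as.integer(window_samples)
  if (w < 1L) stop("window must be positive")
  if (w %% 2L == 0L) {
    warning("even moving-average window adjusted up by 1")
    w <- w + 1L
  }
  if (w > n) stop("moving-average window exceeds signal length")
  if (w == 1L) return(as.numeric(x))
  h <- (w - 1L) %/% 2L
  # reflect (without repeating the edge sample): x[h+1..2], x, x[n-1..n-h]
  xp <- c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
  cs <- cumsum(c(0, xp))
  (cs[(w + 1L):(n + w)] - cs[1L:n]) / w
}

ms_to_odd_samples <- function(ms, fs) {
  w <- as.integer(round(ms * fs / 1000))
  if (w %% 2L == 0L) w <- w + 1L
  max(w, 1L)
}

#' Detect beat peaks with two event-related moving averages
#'
#' Block-based detector: the input (already bandpass-filtered at the working
#' rate) is optionally clipped at zero and, for PPG, squared; a short moving
#' average (window `w1_ms`) tracks peak-scale energy and a long one
#' (`w2_ms`) tracks beat-scale energy. Runs where the short average strictly
#' exceeds the long one form blocks of interest; blocks narrower than
#' `W1 + beta` samples are rejected, and each surviving block contributes
#' one peak at the argmax of the original filtered signal (earliest index on
#' ties).
#'
#' @param signal An [af_signal()], bandpass-filtered at the working rate.
#' @param config A [peak_detect_config()].
#' @return A [peak_list()] with 0-based indices, times in ms, and the
#'   filtered-signal amplitudes at the peaks.
#' @export
detect_peaks <- function(signal, config = peak_detect_config(signal$modality)) {
  stopifnot(inherits(signal, "af_signal"), inherits(config, "peak_detect_config"))
  fs <- signal$fs
  w1 <- as.integer(round(config$w1_ms * fs / 1000))
  if (w1 < 3L) {
    stop(sprintf(
      "sampling rate %g Hz too low: peak window W1 spans < 3 samples (>= 50 Hz required)",
      fs))
  }
  w1 <- ms_to_odd_samples(config$w1_ms, fs)
  w2 <- ms_to_odd_samples(config$w2_ms, fs)
  x <- signal$samples
  n <- length(x)
  if (w2 > n) stop("signal shorter than the beat-scale window")

  y <- x
  if (config$clip_negatives) y <- pmax(y, 0)
  if (config$squaring) y <- y * y
  ma_peak <- moving_average(y, w1)
  ma_beat <- moving_average(y, w2)

  interest <- ma_peak > ma_beat
  if (!any(interest)) {
    return(peak_list())
  }
  r <- rle(interest)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= (w1 + round(config$beta_ms * fs / 1000))
  starts <- starts[keep]
  ends <- ends[keep]
  if (!length(starts)) return(peak_list())

  idx <- integer(length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:ends[j]]
    idx[j] <- starts[j] + which.max(seg) - 1L   # which.max: earliest tie
  }
  idx0 <- idx - 1L                              # 0-based
  peak_list(indices = idx0,
            times_ms = signal$t0_ms + 1000 * idx0 / fs,
            amplitudes = x[idx])
}

#' Convert a peak list to successive inter-beat intervals
#'
#' @param peaks A [peak_list()] with at least 2 peaks.
#' @return An [rr_series()] with `N = n_peaks - 1` intervals in ms.
#' @export
peaks_to_rr <- function(peaks) {
  stopifnot(inherits(peaks, "peak_list"))
  if (length(peaks$times_ms) < 2L) {
    stop("need at least 2 peaks to form intervals")
  }
  rr_series(diff(peaks$times_ms))
}
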