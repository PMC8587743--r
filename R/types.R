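#' Sampled physiological signal
#'
#' Lightweight container for a single-channel sampled waveform. Time of
#' sample `i` (0-based) is `t0_ms + 1000 * i / fs`.
#'
#' @param samples Numeric vector of sample values (arbitrary sensor units).
#' @param fs Sampling rate in Hz (> 0).
#' @param modality `"ECG"` or `"PPG"`.
#' @param t0_ms Time of sample 0 in milliseconds.
#' @return An object of class `af_signal`.
#' @export
af_signal <- function(samples, fs, modality = c("ECG", "PPG"), t0_ms = 0) {
  modality <- match.arg(toupper(modality), c("ECG", "PPG"))
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("signal must contain at least one sample")
  if (!all(is.finite(samples))) stop("signal samples must all be finite")
  if (!is.finite(fs) || fs <= 0) stop("sampling rate fs must be > 0")
  structure(
    list(samples = samples, fs = fs, modality = modality, t0_ms = t0_ms),
    class = "af_signal"
  )
}

#' @export
print.af_signal <- function(x, ...) {
  cat(sprintf(
    "<af_signal> %s, %d samples @ %g Hz (%.1f s), t0 = %g ms\n",
    x$modality, length(x$samples), x$fs, length(x$samples) / x$fs, x$t0_ms
  ))
  invisible(x)
}

#' @export
length.af_signal <- function(x) length(x$samples)

#' Sample times of a signal in milliseconds
#' @param x An `af_signal`.
#' @return Numeric vector of per-sample times (ms).
#' @export
signal_times_ms <- function(x) {
  stopifnot(inherits(x, "af_signal"))
  x$t0_ms + 1000 * (seq_along(x$samples) - 1) / x$fs
}

#' Detected (or ground-truth) beat peak list
#'
#' @param indices 0-based sample indices, strictly increasing.
#' @param times_ms Peak times in milliseconds, strictly increasing.
#' @param amplitudes Signal values at the peaks.
#' @return An object of class `peak_list`.
#' @export
peak_list <- function(indices = integer(), times_ms = numeric(),
                      amplitudes = numeric()) {
  if (length(indices) != length(times_ms) ||
      length(indices) != length(amplitudes)) {
    stop("indices, times_ms and amplitudes must have equal length")
  }
  if (length(times_ms) > 1L && any(diff(times_ms) <= 0)) {
    stop("peak times must be strictly increasing")
  }
  structure(
    list(indices = as.integer(indices), times_ms = as.numeric(times_ms),
         amplitudes = as.numeric(amplitudes)),
    class = "peak_list"
  )
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %d peaks\n", length(x$indices)))
  invisible(x)
}

#' Series of successive inter-beat intervals
#'
#' @param intervals_ms Positive interval durations in milliseconds.
#' @return An object of class `rr_series` with fields `intervals_ms` and `N`.
#' @export
rr_series <- function(intervals_ms) {
  intervals_ms <- as.numeric(intervals_ms)
  if (any(!is.finite(intervals_ms)) || any(intervals_ms <= 0)) {
    stop("all RR intervals must be finite and > 0")
  }
  structure(
    list(intervals_ms = intervals_ms, N = length(intervals_ms)),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> N = %d intervals, mean %.1f ms\n",
              x$N, if (x$N) mean(x$intervals_ms) else NA_real_))
  invisible(x)
}

as_rr <- function(x) {
  if (inherits(x, "rr_series")) x else rr_series(x)
}

#' Beat annotations (times + WFDB beat symbols)
#' @param times_ms Strictly increasing annotation times in ms.
#' @param labels One beat symbol per time (WFDB beat alphabet).
#' @return An object of class `beat_annotations`.
#' @export
beat_annotations <- function(times_ms = numeric(), labels = character()) {
  if (length(times_ms) != length(labels)) {
    stop("times_ms and labels must have equal length")
  }
  if (length(times_ms) > 1L && any(diff(times_ms) <= 0)) {
    stop("annotation times must be strictly increasing")
  }
  structure(list(times_ms = as.numeric(times_ms),
                 labels = as.character(labels)),
            class = "beat_annotations")
}

#' Rhythm intervals (half-open, non-overlapping)
#'
#' @param start_ms,end_ms Interval bounds in ms; each interval is
#'   `[start_ms, end_ms)`.
#' @param rhythm Rhythm class per interval: `"NSR"`, `"AF"` or `"OTHER"`.
#' @return An object of class `rhythm_intervals` (a data.frame).
#' @export
rhythm_intervals <- function(start_ms = numeric(), end_ms = numeric(),
                             rhythm = character()) {
  d <- data.frame(start_ms = as.numeric(start_ms),
                  end_ms = as.numeric(end_ms),
                  rhythm = as.character(rhythm),
                  stringsAsFactors = FALSE)
  if (nrow(d)) {
    if (any(d$start_ms >= d$end_ms)) stop("rhythm intervals need start < end")
    if (!all(d$rhythm %in% c("NSR", "AF", "OTHER"))) {
      stop("rhythm must be one of NSR, AF, OTHER")
    }
    d <- d[order(d$start_ms), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start_ms[-1L] < d$end_ms[-nrow(d)])) {
      stop("rhythm intervals must not overlap")
    }
  }
  class(d) <- c("rhythm_intervals", "data.frame")
  d
}
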