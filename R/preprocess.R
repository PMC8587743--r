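#' Butterworth bandpass specification
#'
#' @param order Filter order (applied forward-backward, so effective order
#'   doubles).
#' @param low_hz,high_hz Passband edges in Hz, `0 < low < high`.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(order, low_hz, high_hz) {
  if (!(order >= 1 && low_hz > 0 && low_hz < high_hz)) {
    stop("need order >= 1 and 0 < low_hz < high_hz")
  }
  structure(list(order = as.integer(order), low_hz = low_hz,
                 high_hz = high_hz, family = "butterworth"),
            class = "filter_spec")
}

#' Default modality filter specifications
#'
#' ECG: order-2 Butterworth, 8-20 Hz (suppresses baseline drift and P/T
#' waves, keeps QRS energy). PPG: order-3 Butterworth, 0.5-8 Hz.
#'
#' @param modality `"ECG"` or `"PPG"`.
#' @return A [filter_spec()].
#' @export
default_filter_spec <- function(modality = c("ECG", "PPG")) {
  modality <- match.arg(toupper(modality), c("ECG", "PPG"))
  if (modality == "ECG") filter_spec(2, 8, 20) else filter_spec(3, 0.5, 8)
}

#' Zero-phase Butterworth bandpass filtering
#'
#' Applies the Butterworth design forward and backward (zero phase, so peak
#' times are not shifted). The signal is extended at both ends by odd
#' reflection before filtering and trimmed afterwards, which suppresses edge
#' transients.
#'
#' @param signal An [af_signal()].
#' @param spec A [filter_spec()]; default chosen by the signal's modality.
#' @return Filtered [af_signal()], same length and rate.
#' @export
bandpass_filter <- function(signal, spec = default_filter_spec(signal$modality)) {
  stopifnot(inherits(signal, "af_signal"), inherits(spec, "filter_spec"))
  fs <- signal$fs
  if (spec$high_hz >= fs / 2) {
    stop(sprintf("high cutoff %g Hz must be below Nyquist (%g Hz)",
                 spec$high_hz, fs / 2))
  }
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  x <- signal$samples
  n <- length(x)
  pad <- min(n - 1L, 3L * (max(length(bf$a), length(bf$b)) - 1L) * 10L)
  if (pad > 0L) {
    head_ext <- 2 * x[1L] - x[(pad + 1L):2L]
    tail_ext <- 2 * x[n] - x[(n - 1L):(n - pad)]
    xp <- c(head_ext, x, tail_ext)
  } else {
    xp <- x
  }
  yp <- signal::filtfilt(bf, xp)
  y <- yp[(pad + 1L):(pad + n)]
  af_signal(y, fs, signal$modality, signal$t0_ms)
}

#' Fourier-domain resampling
#'
#' Resamples to `round(n * target_fs / fs)` samples by truncating or
#' zero-padding the discrete Fourier spectrum (the FFT method): band-limited
#' content below the new Nyquist rate is preserved exactly up to edge
#' effects. Upsampling is permitted but warned about.
#'
#' @param signal An [af_signal()] of length >= 2.
#' @param target_fs Target sampling rate in Hz.
#' @return Resampled [af_signal()] at `target_fs`.
#' @export
resample_fft <- function(signal, target_fs) {
  stopifnot(inherits(signal, "af_signal"))
  if (!is.finite(target_fs) || target_fs <= 0) stop("target_fs must be > 0")
  x <- signal$samples
  n <- length(x)
  if (n < 2L) stop("resampling needs at least 2 samples")
  if (target_fs > signal$fs) {
    warning("upsampling above the native rate adds no information")
  }
  m <- as.integer(round(n * target_fs / signal$fs))
  if (m < 1L) stop("target rate yields an empty signal")
  if (m == n) {
    return(af_signal(x, target_fs, signal$modality, signal$t0_ms))
  }
  X <- stats::fft(x)
  Y <- complex(m)
  nh <- min(n, m)
  h <- nh %/% 2L
  if (nh %% 2L == 1L) {
    # odd: DC + h positive + h negative bins, no shared Nyquist bin
    Y[1:(h + 1L)] <- X[1:(h + 1L)]
    if (h >= 1L) Y[(m - h + 1L):m] <- X[(n - h + 1L):n]
  } else {
    # even: DC + (h-1) positive, (h-1) negative, then the Nyquist bin
    Y[1:h] <- X[1:h]
    if (h >= 2L) Y[(m - h + 2L):m] <- X[(n - h + 2L):n]
    if (m < n) {
      # old +h and -h frequency bins fold onto the new Nyquist bin
      Y[h + 1L] <- X[h + 1L] + X[n - h + 1L]
    } else {
      # old Nyquist bin splits across the new +h and -h bins
      Y[h + 1L] <- X[h + 1L] / 2
      Y[m - h + 1L] <- Conj(X[h + 1L] / 2)
    }
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / n
  af_signal(y, target_fs, signal$modality, signal$t0_ms)
}

#' Fit per-feature z-score normalisation statistics
#'
#' Means and sample standard deviations per column, intended to be fit on a
#' declared training partition only and then applied to held-out data.
#' Constant columns get sd 1 with a warning.
#'
#' @param features Numeric matrix, one row per segment, 12 feature columns.
#' @return A `norm_stats` object (`mean`, `sd` vectors).
#' @export
zscore_fit <- function(features) {
  features <- as.matrix(features)
  if (ncol(features) != 12L) stop("feature matrix must have 12 columns")
  if (nrow(features) < 2L) stop("need at least 2 rows to fit normalisation")
  if (!all(is.finite(features))) stop("non-finite feature values")
  mu <- colMeans(features)
  sdv <- apply(features, 2L, stats::sd)
  if (any(sdv == 0)) {
    warning("constant feature column(s); sd replaced by 1")
    sdv[sdv == 0] <- 1
  }
  structure(list(mean = mu, sd = sdv, names = colnames(features)),
            class = "norm_stats")
}

#' Apply z-score normalisation
#' @param features Numeric matrix with 12 columns.
#' @param stats A `norm_stats` from [zscore_fit()].
#' @return Normalised matrix, same shape.
#' @export
zscore_apply <- function(features, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  features <- as.matrix(features)
  if (ncol(features) != 12L) stop("feature matrix must have 12 columns")
  sweep(sweep(features, 2L, stats$mean, "-"), 2L, stats$sd, "/")
}
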