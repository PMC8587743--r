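#' @name hrv
#' @title Time-domain HRV/PRV features
#'
#' @description Twelve time-domain heart-rate-variability (pulse-rate-
#' variability for PPG) statistics computed from a series of successive
#' inter-beat intervals in milliseconds. The fixed feature order used
#' everywhere in the package is given by [hrv_feature_names()].
#'
#' Conventions: standard deviations use the sample (n - 1) denominator;
#' rMSSD divides the summed squared successive differences by N - 1 where N
#' is the number of intervals; RR20/RR50 count successive-difference
#' magnitudes strictly greater than 20/50 ms; pRR20/pRR50 divide those
#' counts by N (set `prr_denominator = "n-1"` for the conventional pNN50
#' denominator); madRR is the raw median absolute deviation about the
#' median (no normal-consistency factor).
NULL

#' Fixed HRV feature order
#' @return Character vector of the 12 feature names in canonical order.
#' @export
hrv_feature_names <- function() {
  c("meanRR", "medianRR", "madRR", "mcvRR", "SDRR", "rMSSD",
    "CVRR", "CVSD", "RR20", "pRR20", "RR50", "pRR50")
}

#' Root mean square of successive interval differences (rMSSD)
#'
#' `sqrt( sum_{i=1..N-1} (RR_i - RR_{i+1})^2 / (N - 1) )`, in ms.
#'
#' @param rr An [rr_series()] or numeric vector of intervals in ms (N >= 2).
#' @return rMSSD in milliseconds.
#' @export
compute_rmssd <- function(rr) {
  rr <- as_rr(rr)
  if (rr$N < 2L) stop("rMSSD needs at least 2 intervals")
  d <- diff(rr$intervals_ms)
  sqrt(sum(d^2) / (rr$N - 1))
}

#' Sample standard deviation of intervals (SDRR)
#'
#' @inheritParams compute_rmssd
#' @return SDRR in milliseconds (n - 1 denominator).
#' @export
compute_sdrr <- function(rr) {
  rr <- as_rr(rr)
  if (rr$N < 2L) stop("SDRR needs at least 2 intervals")
  stats::sd(rr$intervals_ms)
}

#' Compute the 12 time-domain HRV features
#'
#' @inheritParams compute_rmssd
#' @param prr_denominator `"n"` (default; counts divided by the number of
#'   intervals) or `"n-1"` (divided by the number of successive differences,
#'   the conventional pNN50 form).
#' @return Named numeric vector of length 12 in [hrv_feature_names()] order.
#' @export
compute_features <- function(rr, prr_denominator = c("n", "n-1")) {
  prr_denominator <- match.arg(prr_denominator)
  rr <- as_rr(rr)
  if (rr$N < 4L) stop("feature extraction needs at least 4 intervals")
  x <- rr$intervals_ms
  meanRR <- mean(x)
  medianRR <- stats::median(x)
  if (meanRR == 0 || medianRR == 0) stop("degenerate interval series")
  madRR <- stats::median(abs(x - medianRR))
  sdrr <- stats::sd(x)
  rmssd <- compute_rmssd(rr)
  d <- abs(diff(x))
  denom <- if (prr_denominator == "n") rr$N else rr$N - 1L
  rr20 <- sum(d > 20)
  rr50 <- sum(d > 50)
  out <- c(
    meanRR = meanRR, medianRR = medianRR, madRR = madRR,
    mcvRR = madRR / medianRR, SDRR = sdrr, rMSSD = rmssd,
    CVRR = sdrr / meanRR, CVSD = rmssd / meanRR,
    RR20 = rr20, pRR20 = rr20 / denom, RR50 = rr50, pRR50 = rr50 / denom
  )
  out[hrv_feature_names()]
}
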