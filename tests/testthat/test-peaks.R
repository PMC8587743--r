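test_that("moving average matches hand-computed values", {
  expect_equal(moving_average(rep(4, 10), 5), rep(4, 10))
  expect_equal(moving_average(c(0, 0, 1, 0, 0), 3), c(0, 1/3, 1/3, 1/3, 0))
  expect_equal(moving_average(c(3, 1, 4, 1, 5), 1), c(3, 1, 4, 1, 5))
  expect_warning(y <- moving_average(1:10, 4), "adjusted")
  expect_length(y, 10)
  expect_error(moving_average(1:3, 5), "exceeds")
})

test_that("detector recovers clean beat trains exactly across 40-180 bpm", {
  for (modality in c("ECG", "PPG")) {
    for (bpm in seq(40, 180, by = 20)) {
      wf <- steady_train(bpm, modality = modality)
      pk <- detect_peaks(bandpass_filter(wf$signal))
      st <- match_peaks(pk$indices, wf$truth$indices, tol_samples = 1)
      expect_equal(unname(st["recall"]), 1,
                   info = sprintf("%s %d bpm recall", modality, bpm))
      expect_equal(unname(st["precision"]), 1,
                   info = sprintf("%s %d bpm precision", modality, bpm))
    }
  }
})

test_that("degenerate and bounds cases behave as contracted", {
  zero <- af_signal(rep(0, 1500), 50, "ECG")
  pk <- detect_peaks(zero)
  expect_length(pk$indices, 0)

  expect_error(detect_peaks(af_signal(rnorm(300), 20, "ECG")), "50 Hz")

  wf <- steady_train(75)
  f <- bandpass_filter(wf$signal)
  pk <- detect_peaks(f)
  expect_gte(min(diff(pk$indices)), 5)   # blocks are disjoint, >= W1 apart
  expect_true(all(diff(pk$times_ms) > 0))
})

test_that("detection is invariant to positive amplitude scaling", {
  wf <- steady_train(90)
  f <- bandpass_filter(wf$signal)
  pk1 <- detect_peaks(f)
  for (c in c(0.01, 3, 1000)) {
    fc <- af_signal(c * f$samples, f$fs, f$modality)
    pkc <- detect_peaks(fc)
    expect_identical(pkc$indices, pk1$indices)
  }
})

test_that("detector matches a local-argmax oracle on isolated-peak signals", {
  # impulse-like beats: true peaks are strict local maxima above everything
  set.seed(55)
  fs <- 50
  n <- 1500
  x <- rep(0, n)
  truth <- sort(sample(seq(50, n - 50, by = 45), 20))
  x[truth] <- runif(20, 0.8, 1.2)
  x <- stats::filter(x, dnorm(-3:3, sd = 1.2), sides = 2)
  x[is.na(x)] <- 0
  sig <- af_signal(as.numeric(x), fs, "ECG")
  pk <- detect_peaks(sig)
  thr <- max(x) / 2
  oracle <- which(x > thr &
                  x >= c(-Inf, head(x, -1)) & x > c(tail(x, -1), -Inf)) - 1L
  expect_identical(pk$indices, as.integer(oracle))
})

test_that("noisy recovery stays above 95% across seeded trials", {
  recalls <- vapply(1:100, function(s) {
    rrv <- gen_rr_series(rr_model("NSR"), 40, seed = 3000 + s)
    wf <- gen_waveform(rrv, waveform_model(snr_db = 20), fs = 50,
                       modality = "ECG", duration_ms = 30000,
                       start_ms = 400, seed = 7000 + s)
    pk <- detect_peaks(bandpass_filter(wf$signal))
    match_peaks(pk$indices, wf$truth$indices, tol_samples = 2)["recall"]
  }, numeric(1))
  expect_gte(mean(recalls), 0.95)
})

test_that("peaks_to_rr is the successive-difference map", {
  pk <- peak_list(indices = c(0L, 40L, 80L), times_ms = c(0, 800, 1600),
                  amplitudes = c(1, 1, 1))
  expect_equal(peaks_to_rr(pk)$intervals_ms, c(800, 800))
  pk2 <- peak_list(indices = c(0L, 40L, 95L), times_ms = c(0, 800, 1900),
                   amplitudes = c(1, 1, 1))
  expect_equal(peaks_to_rr(pk2)$intervals_ms, c(800, 1100))
  many <- peak_list(indices = 0:38 * 40L, times_ms = 0:38 * 800,
                    amplitudes = rep(1, 39))
  expect_identical(peaks_to_rr(many)$N, 38L)
  one <- peak_list(indices = 0L, times_ms = 0, amplitudes = 1)
  expect_error(peaks_to_rr(one), "2 peaks")
})
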