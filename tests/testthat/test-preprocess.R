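test_that("bandpass filter suppresses out-of-band and keeps in-band content", {
  fs <- 250
  t <- (0:(30 * fs - 1)) / fs
  trim <- (5 * fs):(25 * fs)   # central stretch, away from edge transients

  dc <- af_signal(rep(2, length(t)), fs, "ECG")
  y <- bandpass_filter(dc)$samples
  expect_lt(max(abs(y[trim])), 2e-6)

  s12 <- af_signal(sin(2 * pi * 12 * t), fs, "ECG")
  y12 <- bandpass_filter(s12)$samples
  rms_ratio <- sqrt(mean(y12[trim]^2)) / sqrt(mean(s12$samples[trim]^2))
  # designed order-2 response at 12 Hz (8-20 Hz band) is near unity
  expect_gt(rms_ratio, 0.85)
  expect_lt(rms_ratio, 1.15)

  drift <- af_signal(sin(2 * pi * 0.05 * t) + sin(2 * pi * 12 * t), fs, "ECG")
  yd <- bandpass_filter(drift)$samples
  spec_in <- Mod(stats::fft(drift$samples))
  spec_out <- Mod(stats::fft(yd))
  bin_drift <- round(0.05 * 30) + 1    # 0.05 Hz bin of the 30-s record
  atten_db <- 20 * log10(spec_in[bin_drift] / spec_out[bin_drift])
  expect_gt(atten_db, 40)

  expect_error(bandpass_filter(af_signal(rnorm(100), 30, "ECG")),
               "Nyquist")
})

test_that("filtering is linear within numerical tolerance", {
  set.seed(31)
  fs <- 100
  x <- rnorm(2000)
  y <- rnorm(2000)
  a <- 2.5; b <- -1.25
  fx <- bandpass_filter(af_signal(x, fs, "ECG"))$samples
  fy <- bandpass_filter(af_signal(y, fs, "ECG"))$samples
  fxy <- bandpass_filter(af_signal(a * x + b * y, fs, "ECG"))$samples
  expect_equal(fxy, a * fx + b * fy, tolerance = 1e-9)
})

test_that("FFT resampling has the contracted length and preserves content", {
  fs <- 128
  x <- af_signal(sin(2 * pi * 5 * (0:3839) / fs), fs, "ECG")
  r <- resample_fft(x, 50)
  expect_identical(length(r$samples), 1500L)   # round(3840 * 50 / 128)
  expect_equal(r$fs, 50)
  spec <- Mod(stats::fft(r$samples))
  dom_hz <- (which.max(spec[1:750]) - 1) * 50 / 1500
  expect_equal(dom_hz, 5)

  const <- resample_fft(af_signal(rep(3.5, 640), fs, "ECG"), 50)
  expect_equal(const$samples, rep(3.5, 250), tolerance = 1e-9)

  expect_warning(resample_fft(af_signal(rnorm(100), 50, "ECG"), 128),
                 "upsampling")
  # odd lengths and non-integer ratios still honour the length contract
  for (n in c(997, 1000, 1501)) {
    r2 <- resample_fft(af_signal(rnorm(n), 128, "ECG"), 50)
    expect_identical(length(r2$samples), as.integer(round(n * 50 / 128)))
  }
})

test_that("band-limited round-trip resampling recovers the signal", {
  fs <- 128
  t <- (0:(30 * fs - 1)) / fs
  x <- sin(2 * pi * 3 * t) + 0.5 * cos(2 * pi * 11 * t)
  s <- af_signal(x, fs, "ECG")
  down <- resample_fft(s, 50)
  up <- suppressWarnings(resample_fft(down, 128))
  mid <- (length(x) %/% 4):(3 * length(x) %/% 4)
  rms_err <- sqrt(mean((up$samples[mid] - x[mid])^2)) / sqrt(mean(x[mid]^2))
  expect_lt(rms_err, 0.01)
})

test_that("z-score fit/apply honours the sample-sd convention", {
  m <- matrix(rep(c(1, 2, 3), 12), nrow = 3)
  st <- zscore_fit(m)
  z <- zscore_apply(m, st)
  expect_equal(z[, 1], c(-1, 0, 1))
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_equal(apply(z, 2, sd), rep(1, 12), tolerance = 1e-9)

  # idempotence: refitting already-standardised data changes nothing
  st2 <- zscore_fit(z)
  expect_equal(zscore_apply(z, st2), z, tolerance = 1e-9)

  mc <- m; mc[, 4] <- 7
  expect_warning(stc <- zscore_fit(mc), "constant")
  expect_equal(zscore_apply(mc, stc)[, 4], rep(0, 3))

  expect_error(zscore_fit(matrix(1:10, 5, 2)), "12 columns")
})

test_that("powerline injected at the native rate dies in the chain", {
  fs <- 250
  rrv <- gen_rr_series(rr_model("NSR"), 40, seed = 11)
  clean <- gen_waveform(rrv, waveform_model(), fs = fs, modality = "ECG",
                        duration_ms = 30000, start_ms = 400)
  noisy <- gen_waveform(rrv, waveform_model(powerline_hz = 50,
                                            powerline_amp = 0.5),
                        fs = fs, modality = "ECG", duration_ms = 30000,
                        start_ms = 400)
  chain <- function(s) resample_fft(bandpass_filter(s), 50)$samples
  # 50 Hz power in the raw render vs after filter + resample to 50 Hz
  raw_amp <- Mod(stats::fft(noisy$signal$samples - clean$signal$samples))
  out <- chain(noisy$signal)
  out_clean <- chain(clean$signal)
  resid <- Mod(stats::fft(out - out_clean))
  atten_db <- 20 * log10(max(raw_amp) / max(resid))
  expect_gt(atten_db, 30)
})
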