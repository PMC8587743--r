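#' RR-interval generative model
#'
#' Normal sinus rhythm (NSR) is modelled as a stationary AR(1) Gaussian
#' process around a normative mean: successive beats are positively
#' correlated, which keeps successive-difference statistics (rMSSD) inside
#' published short-term reference bands. Atrial fibrillation (AF) has no
#' published RR distribution here; it is modelled as i.i.d. draws with high
#' variance plus an occasional uniform "jump" component (very short or long
#' intervals), reflecting the irregular, weakly correlated beat-to-beat
#' intervals that define the arrhythmia. The AF parameterisation is
#' synthetic scaffolding, not an estimate from patient data.
#'
#' @param class_label `"NSR"` or `"AF"`.
#' @param mean_ms,sd_ms Marginal mean and SD of the interval distribution.
#' @param rho AR(1) lag-1 correlation (0 for i.i.d.).
#' @param floor_ms Hard lower clip for generated intervals.
#' @param jump_weight Mixture weight of the uniform jump component (AF).
#' @param jump_range_ms Range of the jump component, ms.
#' @return An `rr_model` list.
#' @export
rr_model <- function(class_label = c("NSR", "AF"),
                     mean_ms = NULL, sd_ms = NULL, rho = NULL,
                     floor_ms = NULL, jump_weight = NULL,
                     jump_range_ms = c(350, 1400)) {
  class_label <- match.arg(toupper(class_label), c("NSR", "AF"))
  if (class_label == "NSR") {
    if (is.null(mean_ms)) mean_ms <- 926
    if (is.null(sd_ms)) sd_ms <- 90
    if (is.null(rho)) rho <- 0.7
    if (is.null(floor_ms)) floor_ms <- 400
    if (is.null(jump_weight)) jump_weight <- 0
  } else {
    if (is.null(mean_ms)) mean_ms <- 700
    if (is.null(sd_ms)) sd_ms <- 180
    if (is.null(rho)) rho <- 0
    if (is.null(floor_ms)) floor_ms <- 300
    if (is.null(jump_weight)) jump_weight <- 0.2
  }
  if (mean_ms <= 0 || sd_ms < 0 || rho < 0 || rho >= 1 ||
      jump_weight < 0 || jump_weight > 1) {
    stop("invalid rr_model parameters")
  }
  structure(list(class_label = class_label, mean_ms = mean_ms, sd_ms = sd_ms,
                 rho = rho, floor_ms = floor_ms, jump_weight = jump_weight,
                 jump_range_ms = jump_range_ms),
            class = "rr_model")
}

#' Generate a seeded RR-interval series
#'
#' @param model An [rr_model()].
#' @param n_beats Number of intervals to draw (>= 2).
#' @param seed Integer seed; same seed, same series.
#' @return An [rr_series()].
#' @export
gen_rr_series <- function(model, n_beats, seed = NULL) {
  stopifnot(inherits(model, "rr_model"))
  if (n_beats < 2L) stop("need at least 2 intervals")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_beats)
  if (model$rho > 0) {
    eps <- stats::rnorm(n, 0, model$sd_ms * sqrt(1 - model$rho^2))
    x <- numeric(n)
    x[1L] <- stats::rnorm(1L, 0, model$sd_ms)
    for (i in seq_len(n - 1L)) x[i + 1L] <- model$rho * x[i] + eps[i + 1L]
    out <- model$mean_ms + x
  } else {
    out <- stats::rnorm(n, model$mean_ms, model$sd_ms)
  }
  if (model$jump_weight > 0) {
    jump <- stats::runif(n) < model$jump_weight
    out[jump] <- stats::runif(sum(jump), model$jump_range_ms[1L],
                              model$jump_range_ms[2L])
  }
  rr_series(pmax(out, model$floor_ms))
}

#' Waveform morphology and noise model
#'
#' ECG beats are rendered as a unit-amplitude Gaussian QRS bump (sd
#' `qrs_sigma_ms`) with optional smaller P and T bumps. PPG beats are a
#' systolic/diastolic double pulse: a dominant systolic Gaussian followed by
#' a smaller, broader diastolic Gaussian delayed by ~250 ms. Optional
#' additive noise: white Gaussian at a given SNR, a 0.3 Hz baseline-wander
#' sine, a powerline sine (50/60 Hz, injected at the native rate so the
#' filter chain is exercised), and short motion-artifact bursts.
#'
#' @param qrs_sigma_ms ECG QRS Gaussian sd (ms).
#' @param pt_waves Add P (amp 0.15) and T (amp 0.3) bumps to ECG renders.
#' @param sys_sigma_ms,dia_sigma_ms,dia_amp,dia_delay_ms PPG pulse shape.
#' @param snr_db White-noise SNR in dB (NULL = none).
#' @param baseline_amp Baseline-wander amplitude as a fraction of the beat
#'   amplitude (0.3 Hz sine; 0 = none).
#' @param powerline_hz,powerline_amp Powerline frequency and fractional
#'   amplitude (0 = none).
#' @param motion_rate,motion_amp Expected motion bursts per 30 s and their
#'   fractional amplitude (0 = none).
#' @param pat_jitter_ms Per-beat pulse-arrival-time jitter sd (ms), PPG only;
#'   emulates the variable pulse-transit delay of optical sensors.
#' @return A `waveform_model` list.
#' @export
waveform_model <- function(qrs_sigma_ms = 20, pt_waves = FALSE,
                           sys_sigma_ms = 60, dia_sigma_ms = 90,
                           dia_amp = 0.4, dia_delay_ms = 250,
                           snr_db = NULL, baseline_amp = 0,
                           powerline_hz = 50, powerline_amp = 0,
                           motion_rate = 0, motion_amp = 0,
                           pat_jitter_ms = 0) {
  structure(list(qrs_sigma_ms = qrs_sigma_ms, pt_waves = isTRUE(pt_waves),
                 sys_sigma_ms = sys_sigma_ms, dia_sigma_ms = dia_sigma_ms,
                 dia_amp = dia_amp, dia_delay_ms = dia_delay_ms,
                 snr_db = snr_db, baseline_amp = baseline_amp,
                 powerline_hz = powerline_hz, powerline_amp = powerline_amp,
                 motion_rate = motion_rate, motion_amp = motion_amp,
                 pat_jitter_ms = pat_jitter_ms),
            class = "waveform_model")
}

add_bump <- function(y, fs, center_ms, sigma_ms, amp) {
  n <- length(y)
  half_ms <- 4 * sigma_ms
  i0 <- max(0L, as.integer(floor((center_ms - half_ms) * fs / 1000)))
  i1 <- min(n - 1L, as.integer(ceiling((center_ms + half_ms) * fs / 1000)))
  if (i0 > i1) return(y)
  idx <- i0:i1
  t <- 1000 * idx / fs
  y[idx + 1L] <- y[idx + 1L] + amp * exp(-(t - center_ms)^2 / (2 * sigma_ms^2))
  y
}

#' Render an RR series as an ECG- or PPG-like waveform
#'
#' Beats are placed at the cumulative interval times starting at
#' `start_ms`; the returned ground-truth peak list holds the placed beat
#' times (for PPG with jitter, the jittered systolic times). Noise terms are
#' applied per the [waveform_model()].
#'
#' @param rr An [rr_series()] or numeric interval vector (ms).
#' @param model A [waveform_model()].
#' @param fs Sampling rate for the render (>= 50 Hz).
#' @param modality `"ECG"` or `"PPG"`.
#' @param duration_ms Total signal duration; defaults to last beat time plus
#'   one mean interval.
#' @param start_ms Time of the first beat (default 0).
#' @param seed Optional seed for the noise/jitter draws.
#' @return List with `signal` ([af_signal()]) and `truth` ([peak_list()]).
#' @export
gen_waveform <- function(rr, model = waveform_model(), fs = 50,
                         modality = c("ECG", "PPG"), duration_ms = NULL,
                         start_ms = 0, seed = NULL) {
  modality <- match.arg(toupper(modality), c("ECG", "PPG"))
  rr <- as_rr(rr)
  if (fs < 50) stop("render rate must be >= 50 Hz")
  if (!is.null(seed)) set.seed(seed)
  beat_ms <- start_ms + c(0, cumsum(rr$intervals_ms))
  if (is.null(duration_ms)) {
    duration_ms <- beat_ms[length(beat_ms)] + mean(rr$intervals_ms)
  }
  n <- as.integer(round(duration_ms * fs / 1000))
  if (n < 2L) stop("duration too short")
  beat_ms <- beat_ms[beat_ms < duration_ms]
  if (!length(beat_ms)) stop("no beats fall inside the requested duration")

  if (modality == "PPG" && model$pat_jitter_ms > 0) {
    beat_ms <- beat_ms + stats::rnorm(length(beat_ms), 0, model$pat_jitter_ms)
    beat_ms <- sort(beat_ms)
    beat_ms <- pmax(beat_ms, 0)
    beat_ms <- beat_ms[beat_ms < duration_ms]
  }

  y <- numeric(n)
  for (bm in beat_ms) {
    if (modality == "ECG") {
      y <- add_bump(y, fs, bm, model$qrs_sigma_ms, 1)
      if (model$pt_waves) {
        y <- add_bump(y, fs, bm - 180, 30, 0.15)
        y <- add_bump(y, fs, bm + 250, 70, 0.3)
      }
    } else {
      y <- add_bump(y, fs, bm, model$sys_sigma_ms, 1)
      y <- add_bump(y, fs, bm + model$dia_delay_ms, model$dia_sigma_ms,
                    model$dia_amp)
    }
  }

  t_s <- (seq_len(n) - 1L) / fs
  if (model$baseline_amp > 0) {
    y <- y + model$baseline_amp * sin(2 * pi * 0.3 * t_s +
                                        stats::runif(1, 0, 2 * pi))
  }
  if (model$powerline_amp > 0) {
    y <- y + model$powerline_amp * sin(2 * pi * model$powerline_hz * t_s)
  }
  if (model$motion_rate > 0 && model$motion_amp > 0) {
    k <- stats::rpois(1L, model$motion_rate * (n / fs) / 30)
    if (k > 0) {
      centers <- stats::runif(k, 0, 1000 * n / fs)
      for (cm in centers) y <- add_bump(y, fs, cm, 150, model$motion_amp)
    }
  }
  if (!is.null(model$snr_db)) {
    p_sig <- mean(y^2)
    y <- y + stats::rnorm(n, 0, sqrt(p_sig / 10^(model$snr_db / 10)))
  }

  idx0 <- as.integer(round(beat_ms * fs / 1000))
  idx0 <- pmin(idx0, n - 1L)
  keep <- !duplicated(idx0)
  list(
    signal = af_signal(y, fs, modality),
    truth = peak_list(indices = idx0[keep], times_ms = beat_ms[keep],
                      amplitudes = y[idx0[keep] + 1L])
  )
}

#' Generate a labeled 30-s segment corpus with ground truth
#'
#' Renders `n_nsr` + `n_af` exactly-30-s strips at `native_fs` under the
#' given RR and waveform models. Each segment's beat train starts at a
#' random phase offset inside the first interval (window boundaries do not
#' align with beats, as in real recordings). The manifest records, per
#' segment, the class, the per-segment seed, the true peak times and the 12
#' HRV features computed from the true RR intervals inside the window.
#'
#' @param n_nsr,n_af Segments per class (>= 0).
#' @param nsr_model,af_model [rr_model()]s for the two classes.
#' @param wf_model A [waveform_model()].
#' @param native_fs Render rate (Hz).
#' @param modality `"ECG"` or `"PPG"`.
#' @param seed Master seed; per-segment seeds derive from it.
#' @return List with `segments` (list of `segment_record`) and `manifest`
#'   (data.frame with `segment_id`, `class`, `label`, `seed`, and list
#'   columns `truth_times_ms`, `truth_features`).
#' @export
gen_corpus <- function(n_nsr, n_af,
                       nsr_model = rr_model("NSR"), af_model = rr_model("AF"),
                       wf_model = waveform_model(), native_fs = 128,
                       modality = c("ECG", "PPG"), seed = 1) {
  modality <- match.arg(toupper(modality), c("ECG", "PPG"))
  n_total <- n_nsr + n_af
  if (n_total < 1L) stop("need at least one segment")
  classes <- c(rep("NSR", n_nsr), rep("AF", n_af))
  seeds <- seed * 100003L + seq_len(n_total)   # fixed derivation, 32-bit safe
  win_ms <- 30000

  segments <- vector("list", n_total)
  truth_times <- vector("list", n_total)
  truth_feats <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    m <- if (classes[i] == "NSR") nsr_model else af_model
    set.seed(seeds[i])
    # enough beats to cover 30 s even at the fastest plausible rate
    nb <- as.integer(ceiling(win_ms / max(m$floor_ms, 1)) + 8L)
    rr <- gen_rr_series(m, nb)
    offset <- stats::runif(1, 100, min(rr$intervals_ms[1L], 1000))
    wf <- gen_waveform(rr, wf_model, fs = native_fs, modality = modality,
                       duration_ms = win_ms, start_ms = offset)
    segments[[i]] <- segment_record(wf$signal, label = as.integer(classes[i] == "AF"),
                                    source_id = sprintf("synth-%s-%04d",
                                                        tolower(classes[i]), i),
                                    window_index = 0L)
    truth_times[[i]] <- wf$truth$times_ms
    tf <- tryCatch(compute_features(diff(wf$truth$times_ms)),
                   error = function(e) rep(NA_real_, 12L))
    truth_feats[[i]] <- tf
  }
  manifest <- data.frame(
    segment_id = vapply(segments, function(s) s$source_id, character(1)),
    class = classes,
    label = as.integer(classes == "AF"),
    seed = seeds,
    stringsAsFactors = FALSE
  )
  manifest$truth_times_ms <- truth_times
  manifest$truth_features <- truth_feats
  list(segments = segments, manifest = manifest)
}

#' Generate the wearable-PPG transfer cohort
#'
#' A PPG corpus with a deliberate domain shift relative to the ECG training
#' conditions, emulating a wrist-worn wearable cohort. Per-beat
#' pulse-arrival-time jitter (sd 40 ms, from the variable pulse-transit
#' delay of optical sensing) inflates the pulse-rate variability of normal
#' rhythms, and the AF arm is markedly milder than the ambulatory ECG
#' defaults (rate-controlled / paroxysmal presentation: mean 850 ms, sd
#' 85, jump weight 0.03), so an un-adapted ECG-trained classifier sits on
#' the wrong side of its learned boundary for much of the AF class while
#' the two classes remain separable within the new domain. These conditions
#' are fixed; they define the transfer-learning study, not a tuning
#' surface.
#'
#' @param n_nsr,n_af Segments per class.
#' @param seed Master seed.
#' @param native_fs Render rate (128 Hz, a common wearable PPG rate).
#' @return As [gen_corpus()].
#' @export
gen_transfer_corpus <- function(n_nsr = 96, n_af = 48, seed = 1,
                                native_fs = 128) {
  gen_corpus(n_nsr, n_af,
             nsr_model = rr_model("NSR", mean_ms = 900, sd_ms = 90,
                                  rho = 0.7),
             af_model = rr_model("AF", mean_ms = 850, sd_ms = 85,
                                 jump_weight = 0.03),
             wf_model = waveform_model(pat_jitter_ms = 40),
             native_fs = native_fs, modality = "PPG", seed = seed)
}
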