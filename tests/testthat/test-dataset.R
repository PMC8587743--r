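make_record_signal <- function(minutes, fs = 50) {
  af_signal(rep(0.1, minutes * 60 * fs), fs, "ECG")
}

test_that("window tiling and rhythm labels follow the half-open convention", {
  sig <- make_record_signal(35)
  rh <- rhythm_intervals(0, 35 * 60000, "NSR")
  segs <- segment_windows(sig, rh)
  expect_length(segs, 70)   # floor(2100 s / 30 s)
  expect_true(all(vapply(segs, function(s) s$label == 0L, logical(1))))
  expect_identical(vapply(segs, function(s) s$window_index, integer(1)),
                   0:69)
  # no partial trailing window
  sig2 <- af_signal(rep(0, 50 * 45), 50, "ECG")   # 45 s
  expect_length(segment_windows(sig2, rhythm_intervals(0, 45000, "NSR")), 1)
})

test_that("boundary-straddling and excluded-rhythm windows are dropped", {
  sig <- make_record_signal(2)  # 120 s -> 4 windows
  rh <- rhythm_intervals(c(0, 45000, 90000), c(45000, 90000, 120000),
                         c("NSR", "AF", "OTHER"))
  segs <- segment_windows(sig, rh)
  # window 0 NSR; window 1 straddles NSR/AF; window 2 inside AF; window 3 OTHER
  expect_length(segs, 2)
  expect_identical(vapply(segs, function(s) s$window_index, integer(1)),
                   c(0L, 2L))
  expect_identical(vapply(segs, function(s) s$label, integer(1)), c(0L, 1L))
})

test_that("the S-beat saturation rule uses a strict majority", {
  sig <- make_record_signal(1)  # two windows
  rh <- rhythm_intervals(0, 60000, "NSR")
  mk_beats <- function(n_s, n_n, window = 0) {
    t <- window * 30000 + seq(1000, 29000, length.out = n_s + n_n)
    beat_annotations(t, c(rep("A", n_s), rep("N", n_n)))
  }
  # 6/10 S beats -> saturated -> AF
  segs <- segment_windows(sig, rh, mk_beats(6, 4))
  expect_identical(segs[[1]]$label, 1L)
  # exactly 50% is not "over 50%" -> stays NSR
  segs <- segment_windows(sig, rh, mk_beats(5, 5))
  expect_identical(segs[[1]]$label, 0L)
  # zero S beats -> saturation path ignored -> rhythm label kept
  segs <- segment_windows(sig, rh, mk_beats(0, 10))
  expect_identical(segs[[1]]$label, 0L)
  # beats outside the N/S superclasses disqualify the window from the rule
  t <- seq(1000, 29000, length.out = 10)
  beats <- beat_annotations(t, c(rep("A", 6), rep("N", 3), "V"))
  segs <- segment_windows(sig, rh, beats)
  expect_identical(segs[[1]]$label, 0L)
  # a saturated window with no rhythm annotation at all becomes AF
  segs <- segment_windows(sig, rhythm_intervals(), mk_beats(6, 4))
  expect_length(segs, 1)
  expect_identical(segs[[1]]$label, 1L)
})

test_that("labeling is deterministic and matches generator intent", {
  corp <- gen_corpus(15, 15, seed = 42)
  ds <- build_feature_dataset(corp$segments, pipeline_config())
  keep <- match(ds$kept_ids, corp$manifest$segment_id)
  expect_identical(ds$labels, corp$manifest$label[keep])
  ds2 <- build_feature_dataset(corp$segments, pipeline_config())
  expect_identical(ds$features, ds2$features)
})

test_that("undetectable segments are dropped with a log entry", {
  corp <- gen_corpus(3, 0, seed = 6)
  flat <- segment_record(af_signal(rep(0, 30 * 128), 128, "ECG"),
                         label = 0L, source_id = "flatline")
  ds <- build_feature_dataset(c(corp$segments, list(flat)),
                              pipeline_config())
  expect_identical(length(ds$labels), 3L)
  expect_identical(ds$dropped$segment_id, "flatline")
  expect_match(ds$dropped$reason, "peaks")
  expect_error(build_feature_dataset(list(flat), pipeline_config()),
               "empty dataset")
})

test_that("stratified split keeps proportions, is seeded and exhaustive", {
  labels <- c(rep(0L, 60), rep(1L, 40))
  sp <- stratified_split(labels, 0.8, seed = 5)
  expect_length(sp$train, 80)
  expect_identical(sum(labels[sp$train] == 0L), 48L)
  expect_identical(sum(labels[sp$train] == 1L), 32L)
  expect_identical(sort(c(sp$train, sp$test)), 1:100)
  expect_length(intersect(sp$train, sp$test), 0)
  sp2 <- stratified_split(labels, 0.8, seed = 5)
  expect_identical(sp, sp2)
  sp3 <- stratified_split(labels, 0.8, seed = 6)
  expect_false(identical(sp$train, sp3$train))
  expect_error(stratified_split(rep(1L, 10)), "both classes")
})
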