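#' Training protocol configuration
#'
#' Defaults mirror the published protocol: mini-batch 16, 50 epochs, Adam
#' (lr 1e-3, beta1 0.9, beta2 0.999), binary cross-entropy, stratified
#' 5-fold cross-validation inside a stratified 80/20 outer split. The
#' finetuning (transfer-learning) block uses stratified 4-fold evaluation
#' over a 75/25 split with all layers trainable and a reduced learning rate.
#'
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param cv_folds Inner cross-validation folds.
#' @param train_frac Outer training fraction.
#' @param seed Master seed; per-stage seeds derive from it.
#' @param global_norm Fit z-score stats on all rows (reproduces the original
#'   leaky protocol) instead of the training partition only.
#' @param threshold Decision threshold on the sigmoid output.
#' @param finetune List: `folds`, `train_frac`, `lr_multiplier`, `epochs`,
#'   `reuse_stats` (reuse the ECG normalisation stats instead of refitting
#'   on the new-modality training portion).
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 16L, epochs = 50L, lr = 1e-3,
                         cv_folds = 5L, train_frac = 0.8, seed = 1L,
                         global_norm = FALSE, threshold = 0.5,
                         finetune = list()) {
  ft <- utils::modifyList(
    list(folds = 4L, train_frac = 0.75, lr_multiplier = 0.1, epochs = 50L,
         reuse_stats = FALSE),
    finetune)
  if (cv_folds < 2L || ft$folds < 2L) stop("folds must be >= 2")
  if (train_frac <= 0 || train_frac >= 1) stop("0 < train_frac < 1 required")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 cv_folds = as.integer(cv_folds), train_frac = train_frac,
                 seed = as.integer(seed), global_norm = isTRUE(global_norm),
                 threshold = threshold, finetune = ft),
            class = "train_config")
}

#' Confusion counts (positive class = AF)
#' @param predicted,actual Binary vectors (1 = AF).
#' @return A `confusion_counts` list with TP, FP, FN, TN.
#' @export
confusion_counts <- function(predicted, actual) {
  predicted <- as.integer(predicted)
  actual <- as.integer(actual)
  stopifnot(length(predicted) == length(actual),
            all(predicted %in% 0:1), all(actual %in% 0:1))
  structure(list(TP = sum(predicted == 1L & actual == 1L),
                 FP = sum(predicted == 1L & actual == 0L),
                 FN = sum(predicted == 0L & actual == 1L),
                 TN = sum(predicted == 0L & actual == 0L)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy = (TP+TN)/total, sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), F1 = TP/(TP + 0.5 (FP+FN)); all on the percent scale,
#' rounded to 2 decimals. AF is the positive class. A zero denominator
#' yields `NA` for that metric with a warning, never an error.
#'
#' @param counts A [confusion_counts()] (or list with TP/FP/FN/TN).
#' @return A `metrics_report` list (percent scale).
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN; TN <- counts$TN
  total <- TP + FP + FN + TN
  if (total <= 0) stop("empty confusion table")
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what))
      return(NA_real_)
    }
    round(100 * num / den, 2L)
  }
  structure(list(
    accuracy = safe(TP + TN, total, "accuracy"),
    sensitivity = safe(TP, TP + FN, "sensitivity"),
    specificity = safe(TN, TN + FP, "specificity"),
    f1 = safe(TP, TP + 0.5 * (FP + FN), "F1"),
    counts = counts
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  F1 %.2f%%%s\n",
    x$accuracy, x$sensitivity, x$specificity, x$f1,
    if (!is.null(x$auc) && !is.na(x$auc)) sprintf("  AUC %.2f%%", x$auc) else ""))
  invisible(x)
}

#' Rank-based AUC (Mann-Whitney, ties get half credit)
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (1 = positive/AF).
#' @return AUC as a fraction in [0, 1]; `NA` with a warning if one class is
#'   absent.
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    warning("AUC undefined: one class absent")
    return(NA_real_)
  }
  r <- rank(scores)  # average ranks handle ties as half credit
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin, so fold class proportions differ by at most one sample.
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) stop("a class has fewer samples than folds")
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified train/test split
#'
#' @param labels Binary label vector (both classes present).
#' @param train_frac Training fraction.
#' @param seed Seed for the shuffles.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive, class proportions within one sample of the global ones).
#' @export
stratified_split <- function(labels, train_frac = 0.8, seed = 1) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("stratified split needs both classes present")
  }
  set.seed(seed)
  train <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    n_tr <- round(train_frac * length(idx))
    train <- c(train, idx[seq_len(n_tr)])
  }
  train <- sort(train)
  list(train = train, test = sort(setdiff(seq_along(labels), train)))
}

metrics_from_probs <- function(prob, labels, threshold) {
  m <- compute_metrics(confusion_counts(as.integer(prob >= threshold), labels))
  m$auc <- round(100 * compute_auc(prob, labels), 2L)
  m
}

fold_metrics_df <- function(reports) {
  do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(fold = i, accuracy = r$accuracy, sensitivity = r$sensitivity,
               specificity = r$specificity, f1 = r$f1, auc = r$auc)
  }))
}

summarise_folds <- function(df) {
  cols <- c("accuracy", "sensitivity", "specificity", "f1", "auc")
  data.frame(metric = cols,
             mean = vapply(cols, function(c) mean(df[[c]], na.rm = TRUE),
                           numeric(1)),
             sd = vapply(cols, function(c) stats::sd(df[[c]], na.rm = TRUE),
                         numeric(1)),
             row.names = NULL)
}

#' Train the CNN with stratified cross-validation
#'
#' Protocol: stratified outer split (default 80/20); stratified k-fold
#' cross-validation (default k = 5) inside the training portion, each fold
#' training a fresh network and scoring the held-out part; a final model is
#' refit on the full training portion and scored on the outer holdout.
#' Normalisation statistics are fit on the outer training portion only
#' (set `global_norm = TRUE` in the config for whole-dataset fitting) and
#' stored with the model. Fully seeded.
#'
#' @param features Raw (un-normalised) n x 12 feature matrix.
#' @param labels Binary labels, 1 = AF.
#' @param config A [train_config()].
#' @param spec A [cnn_spec()].
#' @return An `af_cnn_fit`: fitted network, normalisation stats, per-fold
#'   and aggregate CV metrics, holdout metrics, config.
#' @export
train_cv <- function(features, labels, config = train_config(),
                     spec = cnn_spec()) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("need both classes to train")
  stopifnot(nrow(features) == length(labels))

  split <- stratified_split(labels, config$train_frac, config$seed)
  norm <- zscore_fit(if (config$global_norm) features
                     else features[split$train, , drop = FALSE])
  Xn <- zscore_apply(features, norm)
  Xtr <- Xn[split$train, , drop = FALSE]
  ytr <- labels[split$train]

  fold <- stratified_folds(ytr, config$cv_folds, config$seed + 1L)
  reports <- vector("list", config$cv_folds)
  for (f in seq_len(config$cv_folds)) {
    tr <- fold != f
    model_f <- build_model(spec, seed = config$seed * 17L + f)
    model_f <- nn_train(model_f, Xtr[tr, , drop = FALSE], ytr[tr],
                        epochs = config$epochs,
                        batch_size = config$batch_size, lr = config$lr,
                        seed = config$seed * 31L + f)
    prob <- nn_predict(model_f, Xtr[!tr, , drop = FALSE])
    reports[[f]] <- metrics_from_probs(prob, ytr[!tr], config$threshold)
  }
  fold_df <- fold_metrics_df(reports)

  final <- build_model(spec, seed = config$seed)
  final <- nn_train(final, Xtr, ytr, epochs = config$epochs,
                    batch_size = config$batch_size, lr = config$lr,
                    seed = config$seed * 31L)
  prob_hold <- nn_predict(final, Xn[split$test, , drop = FALSE])
  holdout <- metrics_from_probs(prob_hold, labels[split$test],
                                config$threshold)

  structure(list(model = final, spec = spec, norm = norm, config = config,
                 fold_metrics = fold_df, cv_summary = summarise_folds(fold_df),
                 holdout = holdout, split = split),
            class = "af_cnn_fit")
}

#' @export
print.af_cnn_fit <- function(x, ...) {
  cat("<af_cnn_fit> NSR-vs-AF classifier\n")
  cat("cross-validation (mean +/- sd over folds):\n")
  s <- x$cv_summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %6.2f +/- %.2f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  cat("holdout: ")
  print(x$holdout)
  invisible(x)
}

#' Predict AF probability or class for new feature rows
#'
#' @param object An `af_cnn_fit`.
#' @param features Raw n x 12 feature matrix (normalisation applied with the
#'   model's stored stats).
#' @param type `"prob"` or `"class"`.
#' @param ... Ignored.
#' @return Probabilities in (0, 1) or 0/1 labels.
#' @export
predict.af_cnn_fit <- function(object, features, type = c("prob", "class"),
                               ...) {
  type <- match.arg(type)
  prob <- nn_predict(object$model, zscore_apply(as.matrix(features),
                                                object$norm))
  if (type == "prob") prob else as.integer(prob >= object$config$threshold)
}

#' Evaluate a fitted model on a labeled feature set
#'
#' @param fit An `af_cnn_fit`.
#' @param features Raw n x 12 feature matrix.
#' @param labels Binary labels (1 = AF).
#' @param norm Optional `norm_stats` overriding the model's stored stats.
#' @return A `metrics_report` (with AUC).
#' @export
evaluate_model <- function(fit, features, labels, norm = NULL) {
  stopifnot(inherits(fit, "af_cnn_fit"))
  if (is.null(norm)) norm <- fit$norm
  prob <- nn_predict(fit$model, zscore_apply(as.matrix(features), norm))
  metrics_from_probs(prob, as.integer(labels), fit$config$threshold)
}

#' Finetune (transfer) a trained model to a new modality
#'
#' Stratified k-fold scheme (default k = 4) over a 75/25 split: in each
#' fold the pre-trained weights are copied, all layers are retrained on the
#' fold's training portion at a reduced learning rate, and the untouched
#' 25% is scored, so every instance is tested once on weights that never
#' saw it. Normalisation is refit on each fold's training portion by
#' default (`reuse_stats = TRUE` in the finetune config reuses the source
#' stats). A final model finetuned on all rows is returned alongside the
#' fold metrics; `epochs = 0` returns the source weights untouched.
#'
#' @param fit A trained `af_cnn_fit` (source modality).
#' @param features Raw n x 12 feature matrix (target modality).
#' @param labels Binary labels (1 = AF).
#' @param config Optional [train_config()]; defaults to the fit's config.
#' @return List: `model` (an `af_cnn_fit` updated on all rows),
#'   `fold_metrics`, `summary` (mean +/- sd over folds).
#' @export
finetune <- function(fit, features, labels, config = NULL) {
  stopifnot(inherits(fit, "af_cnn_fit"))
  if (is.null(config)) config <- fit$config
  ft <- config$finetune
  features <- as.matrix(features)
  labels <- as.integer(labels)
  lr <- config$lr * ft$lr_multiplier

  fold <- stratified_folds(labels, ft$folds, config$seed + 101L)
  reports <- vector("list", ft$folds)
  for (f in seq_len(ft$folds)) {
    tr <- fold != f
    norm_f <- if (ft$reuse_stats) fit$norm
              else zscore_fit(features[tr, , drop = FALSE])
    model_f <- fit$model
    if (ft$epochs > 0L) {
      model_f <- nn_train(model_f, zscore_apply(features[tr, , drop = FALSE],
                                                norm_f),
                          labels[tr], epochs = ft$epochs,
                          batch_size = config$batch_size, lr = lr,
                          seed = config$seed * 53L + f)
    }
    prob <- nn_predict(model_f, zscore_apply(features[!tr, , drop = FALSE],
                                             norm_f))
    reports[[f]] <- metrics_from_probs(prob, labels[!tr], config$threshold)
  }
  fold_df <- fold_metrics_df(reports)

  norm_all <- if (ft$reuse_stats) fit$norm else zscore_fit(features)
  model_all <- fit$model
  if (ft$epochs > 0L) {
    model_all <- nn_train(model_all, zscore_apply(features, norm_all), labels,
                          epochs = ft$epochs, batch_size = config$batch_size,
                          lr = lr, seed = config$seed * 53L)
  }
  updated <- fit
  updated$model <- model_all
  updated$norm <- norm_all
  list(model = updated, fold_metrics = fold_df,
       summary = summarise_folds(fold_df))
}
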