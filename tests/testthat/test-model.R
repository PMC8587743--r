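test_that("metric formulas reproduce hand-derived and brute-force values", {
  m <- compute_metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(m$accuracy, 100)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)
  expect_equal(m$f1, 100)

  # identities against a per-instance brute-force counter
  set.seed(12)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    truth <- rbinom(n, 1, 0.4)
    pred <- ifelse(runif(n) < 0.3, 1 - truth, truth)
    cc <- confusion_counts(pred, truth)
    tp <- 0; fp <- 0; fn <- 0; tn <- 0
    for (j in seq_len(n)) {
      if (pred[j] == 1 && truth[j] == 1) tp <- tp + 1
      else if (pred[j] == 1 && truth[j] == 0) fp <- fp + 1
      else if (pred[j] == 0 && truth[j] == 1) fn <- fn + 1
      else tn <- tn + 1
    }
    expect_equal(unlist(unclass(cc)), c(TP = tp, FP = fp, FN = fn, TN = tn))
    m <- compute_metrics(cc)
    expect_equal(m$accuracy, round(100 * (tp + tn) / n, 2))
    if (tp + fn > 0) expect_equal(m$sensitivity, round(100 * tp / (tp + fn), 2))
    if (tn + fp > 0) expect_equal(m$specificity, round(100 * tn / (tn + fp), 2))
  }

  w <- testthat::capture_warnings(
    z <- compute_metrics(list(TP = 0, FP = 0, FN = 0, TN = 10)))
  expect_match(w, "sensitivity undefined", all = FALSE)
  expect_match(w, "F1 undefined", all = FALSE)
  expect_true(is.na(z$sensitivity))
  expect_true(is.na(z$f1))
})

test_that("AUC matches pairwise brute force and is rank-invariant", {
  expect_equal(compute_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(compute_auc(rep(0.5, 10), rep(0:1, 5)), 0.5)
  expect_equal(compute_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  set.seed(19)
  for (i in 1:50) {
    n <- sample(10:80, 1)
    s <- round(runif(n), 2)   # rounding forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(compute_auc(s, y), naive_auc(s, y), tolerance = 1e-12)
    # strictly monotone transform leaves AUC unchanged
    expect_equal(compute_auc(exp(3 * s) - 1, y), compute_auc(s, y),
                 tolerance = 1e-12)
  }
  expect_warning(a <- compute_auc(1:4, rep(1, 4)), "one class")
  expect_true(is.na(a))
})

test_that("model building is deterministic with contracted shapes", {
  m1 <- build_model(cnn_spec(), seed = 3)
  m2 <- build_model(cnn_spec(), seed = 3)
  expect_identical(m1$layers, m2$layers)
  m3 <- build_model(cnn_spec(), seed = 4)
  expect_false(identical(m1$layers[[1]]$W, m3$layers[[1]]$W))

  # conv stack shapes: 3*Cin x Cout, dense 192 -> 8 -> 1
  conv_dims <- lapply(Filter(function(l) l$type == "conv", m1$layers),
                      function(l) dim(l$W))
  expect_identical(conv_dims,
                   list(c(3L, 256L), c(768L, 128L), c(384L, 64L), c(192L, 32L)))
  dense_dims <- lapply(Filter(function(l) l$type == "dense", m1$layers),
                       function(l) dim(l$W))
  expect_identical(dense_dims, list(c(192L, 8L), c(8L, 1L)))

  p0 <- pulseaf:::nn_predict(m1, matrix(0, 1, 12))
  expect_true(is.finite(p0) && p0 > 0 && p0 < 1)
  p <- pulseaf:::nn_predict(m1, matrix(rnorm(60), 5, 12))
  expect_true(all(p > 0 & p < 1))
})

test_that("backpropagation matches numerical gradients", {
  spec <- cnn_spec(input_len = 12, conv_filters = c(4L, 3L), dense_units = 5)
  model <- build_model(spec, seed = 8)
  # disable dropout so the loss is deterministic in training mode
  for (i in seq_along(model$layers)) {
    if (model$layers[[i]]$type == "dropout") model$layers[[i]]$rate <- 0
  }
  set.seed(99)
  X <- matrix(rnorm(4 * 12), 4, 12)
  y <- c(0, 1, 1, 0)
  loss_of <- function(m) {
    p <- pulseaf:::nn_forward(m, X, training = TRUE)$prob
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  fwd <- pulseaf:::nn_forward(model, X, training = TRUE)
  grads <- pulseaf:::nn_backward(model, fwd, y)
  eps <- 1e-5
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    field <- switch(ly$type, conv = "W", dense = "W", bn = "gamma", NULL)
    gname <- switch(ly$type, conv = "dW", dense = "dW", bn = "dgamma", NULL)
    if (is.null(field)) next
    set.seed(li)
    for (k in sample(length(ly[[field]]), 3)) {
      mp <- model; mp$layers[[li]][[field]][k] <- ly[[field]][k] + eps
      mm <- model; mm$layers[[li]][[field]][k] <- ly[[field]][k] - eps
      num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      ana <- grads[[li]][[gname]][k]
      expect_equal(ana, num, tolerance = 1e-4,
                   info = sprintf("layer %d (%s) param %d", li, ly$type, k))
    }
  }
})

test_that("training separates well-separated classes and is reproducible", {
  set.seed(64)
  X <- rbind(matrix(rnorm(100 * 12, 0), 100, 12),
             matrix(rnorm(100 * 12, 3), 100, 12))
  y <- c(rep(0L, 100), rep(1L, 100))
  cfg <- train_config(epochs = 10L, seed = 11)
  fit <- train_cv(X, y, cfg)
  expect_gte(fit$holdout$accuracy, 95)
  expect_identical(nrow(fit$fold_metrics), 5L)
  fit2 <- train_cv(X, y, cfg)
  expect_identical(fit$fold_metrics, fit2$fold_metrics)
  expect_identical(fit$holdout$accuracy, fit2$holdout$accuracy)

  # shuffled labels leave nothing to learn: near-chance holdout
  set.seed(65)
  ysh <- sample(y)
  fit_sh <- train_cv(X, ysh, cfg)
  expect_gte(fit_sh$holdout$accuracy, 30)
  expect_lte(fit_sh$holdout$accuracy, 70)
})

test_that("zero-epoch finetuning with reused stats is a no-op", {
  set.seed(66)
  X <- rbind(matrix(rnorm(60 * 12, 0), 60, 12),
             matrix(rnorm(60 * 12, 3), 60, 12))
  y <- c(rep(0L, 60), rep(1L, 60))
  fit <- train_cv(X, y, train_config(epochs = 5L, seed = 21))
  pre <- evaluate_model(fit, X, y)
  ft0 <- finetune(fit, X, y,
                  train_config(epochs = 5L, seed = 21,
                               finetune = list(epochs = 0L,
                                               reuse_stats = TRUE)))
  post <- evaluate_model(ft0$model, X, y)
  expect_identical(pre$accuracy, post$accuracy)
  expect_identical(pre$auc, post$auc)
})

test_that("saved models reload with identical predictions", {
  td <- withr::local_tempdir()
  set.seed(67)
  X <- rbind(matrix(rnorm(40 * 12, 0), 40, 12),
             matrix(rnorm(40 * 12, 2), 40, 12))
  y <- rep(0:1, each = 40)
  fit <- train_cv(X, y, train_config(epochs = 3L, seed = 5))
  path <- file.path(td, "model.json")
  save_model(fit, path)
  back <- load_model(path)
  Xnew <- matrix(rnorm(10 * 12), 10, 12)
  expect_equal(predict(back, Xnew), predict(fit, Xnew), tolerance = 1e-12)
})
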