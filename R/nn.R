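# Internal 1D-CNN engine.
#
# Activations for a batch of B inputs of length L with C channels are stored
# position-major: a (B*L) x C matrix whose row (p-1)*B + b holds sample b at
# position p. Convolution (kernel 3, stride 1, 'same' zero padding) then
# reduces to one BLAS matrix multiply per layer: neighbouring positions are
# whole row-blocks, so the im2col matrix is a cbind of two block-shifted
# copies of the activation matrix.

nn_shift_prev <- function(X, B, L) {
  C <- ncol(X)
  rbind(matrix(0, B, C), X[seq_len(B * (L - 1L)), , drop = FALSE])
}

nn_shift_next <- function(X, B, L) {
  C <- ncol(X)
  rbind(X[(B + 1L):(B * L), , drop = FALSE], matrix(0, B, C))
}

nn_conv_forward <- function(X, W, b, B, L) {
  Xcol <- cbind(nn_shift_prev(X, B, L), X, nn_shift_next(X, B, L))
  Y <- Xcol %*% W
  Y <- sweep(Y, 2L, b, "+")
  list(Y = Y, Xcol = Xcol)
}

nn_conv_backward <- function(dY, cache, W, B, L) {
  Cin <- nrow(W) / 3L
  dW <- crossprod(cache$Xcol, dY)
  db <- colSums(dY)
  dXcol <- tcrossprod(dY, W)
  d_prev <- dXcol[, seq_len(Cin), drop = FALSE]
  d_same <- dXcol[, Cin + seq_len(Cin), drop = FALSE]
  d_next <- dXcol[, 2L * Cin + seq_len(Cin), drop = FALSE]
  dX <- d_same
  lo <- seq_len(B * (L - 1L))
  dX[lo, ] <- dX[lo, ] + d_prev[lo + B, , drop = FALSE]
  dX[lo + B, ] <- dX[lo + B, ] + d_next[lo, , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

nn_bn_forward <- function(X, ly, training, momentum = 0.99, eps = 1e-3) {
  if (training) {
    m <- colMeans(X)
    v <- colMeans(X * X) - m * m
    v <- pmax(v, 0)
  } else {
    m <- ly$run_mean
    v <- ly$run_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(X, 2L, m, "-"), 2L, inv, "*")
  Y <- sweep(sweep(xhat, 2L, ly$gamma, "*"), 2L, ly$beta, "+")
  list(Y = Y, xhat = xhat, inv = inv, m = m, v = v)
}

nn_bn_backward <- function(dY, cache, ly) {
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  n <- nrow(dY)
  t1 <- sweep(dY, 2L, dbeta / n, "-")
  t2 <- sweep(cache$xhat, 2L, dgamma / n, "*")
  dX <- sweep((t1 - t2), 2L, ly$gamma * cache$inv, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

nn_maxpool_idx <- function(B, L) {
  # row indices of odd / even input positions for pool size 2
  q <- seq_len(L %/% 2L)
  ia <- as.vector(outer(seq_len(B), (2L * q - 2L) * B, "+"))
  ib <- as.vector(outer(seq_len(B), (2L * q - 1L) * B, "+"))
  list(ia = ia, ib = ib)
}

nn_dropout_mask <- function(nr, nc, rate) {
  matrix((stats::runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

#' Table-style CNN architecture descriptor
#'
#' The fixed layer stack of the classifier: four kernel-3 stride-1 'same'
#' Conv1D layers (256, 128, 64, 32 filters, ReLU), each followed by batch
#' normalisation, then dropout (rate 0.2), max-pooling (size 2), flatten,
#' a dense ReLU layer of 8 units and a single sigmoid output. Input is the
#' 12-feature HRV vector treated as a length-12, 1-channel sequence.
#'
#' @param input_len Input sequence length (12 features).
#' @param conv_filters Filters of the four convolutional layers.
#' @param dropout_rate Dropout rate after the conv stack.
#' @param dense_units Units of the penultimate dense layer.
#' @return A `cnn_spec` list.
#' @export
cnn_spec <- function(input_len = 12L, conv_filters = c(256L, 128L, 64L, 32L),
                     dropout_rate = 0.2, dense_units = 8L) {
  if (input_len < 3L) stop("input length must be >= kernel size (3)")
  structure(list(input_len = as.integer(input_len),
                 conv_filters = as.integer(conv_filters),
                 kernel = 3L, dropout_rate = dropout_rate,
                 pool = 2L, dense_units = as.integer(dense_units)),
            class = "cnn_spec")
}

#' Build (initialise) the CNN
#'
#' He-normal initial weights for ReLU layers, Glorot for the sigmoid output,
#' zero biases, unit-gamma/zero-beta batch norm. Deterministic in `seed`.
#'
#' @param spec A [cnn_spec()].
#' @param seed Integer seed for the weight draws.
#' @return An `af_cnn` model object (layer list + spec).
#' @export
build_model <- function(spec = cnn_spec(), seed = 1) {
  stopifnot(inherits(spec, "cnn_spec"))
  set.seed(seed)
  layers <- list()
  cin <- 1L
  for (cf in spec$conv_filters) {
    fan_in <- 3L * cin
    layers[[length(layers) + 1L]] <- list(
      type = "conv",
      W = matrix(stats::rnorm(fan_in * cf, 0, sqrt(2 / fan_in)), fan_in, cf),
      b = numeric(cf))
    layers[[length(layers) + 1L]] <- list(
      type = "bn", gamma = rep(1, cf), beta = numeric(cf),
      run_mean = numeric(cf), run_var = rep(1, cf))
    cin <- cf
  }
  layers[[length(layers) + 1L]] <- list(type = "dropout",
                                        rate = spec$dropout_rate)
  layers[[length(layers) + 1L]] <- list(type = "maxpool")
  layers[[length(layers) + 1L]] <- list(type = "flatten")
  flat <- (spec$input_len %/% spec$pool) * cin
  layers[[length(layers) + 1L]] <- list(
    type = "dense", activation = "relu",
    W = matrix(stats::rnorm(flat * spec$dense_units, 0, sqrt(2 / flat)),
               flat, spec$dense_units),
    b = numeric(spec$dense_units))
  glorot <- sqrt(6 / (spec$dense_units + 1))
  layers[[length(layers) + 1L]] <- list(
    type = "dense", activation = "sigmoid",
    W = matrix(stats::runif(spec$dense_units, -glorot, glorot),
               spec$dense_units, 1L),
    b = numeric(1L))
  structure(list(spec = spec, layers = layers), class = "af_cnn")
}

#' @export
print.af_cnn <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l) {
    sum(vapply(l[names(l) %in% c("W", "b", "gamma", "beta")], length,
               numeric(1)))
  }, numeric(1)))
  cat(sprintf("<af_cnn> input %d x 1, %d layers, %d trainable parameters\n",
              x$spec$input_len, length(x$layers), np))
  invisible(x)
}

# Forward pass over a batch. X: B x input_len matrix.
# Returns probabilities and (when training) per-layer caches.
nn_forward <- function(model, X, training = FALSE) {
  spec <- model$spec
  B <- nrow(X)
  L <- spec$input_len
  A <- matrix(as.vector(X), ncol = 1L)  # position-major (B*L) x 1
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$type == "conv") {
      cf <- nn_conv_forward(A, ly$W, ly$b, B, L)
      relu_mask <- cf$Y > 0
      A2 <- cf$Y * relu_mask
      caches[[i]] <- list(Xcol = cf$Xcol, relu_mask = relu_mask)
      A <- A2
    } else if (ly$type == "bn") {
      bf <- nn_bn_forward(A, ly, training)
      caches[[i]] <- bf
      A <- bf$Y
    } else if (ly$type == "dropout") {
      if (training && ly$rate > 0) {
        msk <- nn_dropout_mask(nrow(A), ncol(A), ly$rate)
        caches[[i]] <- list(mask = msk)
        A <- A * msk
      }
    } else if (ly$type == "maxpool") {
      ix <- nn_maxpool_idx(B, L)
      Aa <- A[ix$ia, , drop = FALSE]
      Ab <- A[ix$ib, , drop = FALSE]
      sel_a <- Aa >= Ab
      caches[[i]] <- list(ix = ix, sel_a = sel_a, n_in = nrow(A))
      A <- pmax(Aa, Ab)
      L <- L %/% 2L
    } else if (ly$type == "flatten") {
      caches[[i]] <- list(L = L, C = ncol(A))
      dim(A) <- c(B, L * ncol(A))
      L <- 1L
    } else if (ly$type == "dense") {
      Z <- sweep(A %*% ly$W, 2L, ly$b, "+")
      if (ly$activation == "relu") {
        relu_mask <- Z > 0
        caches[[i]] <- list(A_in = A, relu_mask = relu_mask)
        A <- Z * relu_mask
      } else {
        caches[[i]] <- list(A_in = A)
        A <- 1 / (1 + exp(-Z))
      }
    }
  }
  list(prob = as.vector(A), caches = caches)
}

# Backward pass from binary cross-entropy on sigmoid output.
# Returns list of gradients parallel to model$layers, plus batch-norm batch
# statistics for the running-average update.
nn_backward <- function(model, fwd, y) {
  B <- length(y)
  grads <- vector("list", length(model$layers))
  # d(BCE)/d(logit) for the final sigmoid layer
  dA <- matrix((fwd$prob - y) / B, ncol = 1L)
  L <- 1L
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    ca <- fwd$caches[[i]]
    if (ly$type == "dense") {
      if (ly$activation == "relu") dA <- dA * ca$relu_mask
      grads[[i]] <- list(dW = crossprod(ca$A_in, dA), db = colSums(dA))
      dA <- tcrossprod(dA, ly$W)
    } else if (ly$type == "flatten") {
      dim(dA) <- c(B * ca$L, ca$C)
      L <- ca$L
    } else if (ly$type == "maxpool") {
      dX <- matrix(0, ca$n_in, ncol(dA))
      dX[ca$ix$ia, ] <- dA * ca$sel_a
      dX[ca$ix$ib, ] <- dX[ca$ix$ib, ] + dA * !ca$sel_a
      dA <- dX
      L <- 2L * L
    } else if (ly$type == "dropout") {
      if (!is.null(ca)) dA <- dA * ca$mask
    } else if (ly$type == "bn") {
      bb <- nn_bn_backward(dA, ca, ly)
      grads[[i]] <- list(dgamma = bb$dgamma, dbeta = bb$dbeta,
                         batch_mean = ca$m, batch_var = ca$v)
      dA <- bb$dX
    } else if (ly$type == "conv") {
      dA <- dA * ca$relu_mask
      cb <- nn_conv_backward(dA, ca, ly$W, B, L)
      grads[[i]] <- list(dW = cb$dW, db = cb$db)
      dA <- cb$dX
    }
  }
  grads
}

nn_adam_init <- function(model) {
  st <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$type == "conv" || ly$type == "dense") {
      st[[i]] <- list(mW = ly$W * 0, vW = ly$W * 0,
                      mb = ly$b * 0, vb = ly$b * 0)
    } else if (ly$type == "bn") {
      st[[i]] <- list(mg = ly$gamma * 0, vg = ly$gamma * 0,
                      mb = ly$beta * 0, vb = ly$beta * 0)
    }
  }
  list(t = 0L, st = st)
}

adam_step <- function(m, v, g, t, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(m = m, v = v, delta = lr * mhat / (sqrt(vhat) + eps))
}

nn_adam_update <- function(model, adam, grads, lr, bn_momentum = 0.99) {
  adam$t <- adam$t + 1L
  t <- adam$t
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    g <- grads[[i]]
    if (is.null(g)) next
    s <- adam$st[[i]]
    if (ly$type %in% c("conv", "dense")) {
      up <- adam_step(s$mW, s$vW, g$dW, t, lr)
      s$mW <- up$m; s$vW <- up$v
      ly$W <- ly$W - up$delta
      up <- adam_step(s$mb, s$vb, g$db, t, lr)
      s$mb <- up$m; s$vb <- up$v
      ly$b <- ly$b - up$delta
    } else if (ly$type == "bn") {
      up <- adam_step(s$mg, s$vg, g$dgamma, t, lr)
      s$mg <- up$m; s$vg <- up$v
      ly$gamma <- ly$gamma - up$delta
      up <- adam_step(s$mb, s$vb, g$dbeta, t, lr)
      s$mb <- up$m; s$vb <- up$v
      ly$beta <- ly$beta - up$delta
      ly$run_mean <- bn_momentum * ly$run_mean + (1 - bn_momentum) * g$batch_mean
      ly$run_var <- bn_momentum * ly$run_var + (1 - bn_momentum) * g$batch_var
    }
    model$layers[[i]] <- ly
    adam$st[[i]] <- s
  }
  list(model = model, adam = adam)
}

# Mini-batch Adam training. X: n x input_len (already normalised), y in {0,1}.
nn_train <- function(model, X, y, epochs = 50L, batch_size = 16L,
                     lr = 1e-3, seed = 1, adam = NULL) {
  set.seed(seed)
  n <- nrow(X)
  if (is.null(adam)) adam <- nn_adam_init(model)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (s0 in seq(1L, n, by = batch_size)) {
      idx <- ord[s0:min(s0 + batch_size - 1L, n)]
      if (length(idx) < 2L) next  # batch norm needs > 1 sample
      fwd <- nn_forward(model, X[idx, , drop = FALSE], training = TRUE)
      grads <- nn_backward(model, fwd, y[idx])
      up <- nn_adam_update(model, adam, grads, lr)
      model <- up$model
      adam <- up$adam
    }
  }
  model
}

# Inference-mode probabilities for a feature matrix.
nn_predict <- function(model, X) {
  nn_forward(model, as.matrix(X), training = FALSE)$prob
}
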