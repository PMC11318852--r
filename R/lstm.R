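# Compact batched LSTM sequence classifier.
#
# Architecture: masking (a timestep whose features all equal the mask
# sentinel is skipped: hidden and cell state carry through unchanged), one
# LSTM layer, layer normalization of the final hidden state to stabilize
# its dynamics, a ReLU dense layer, and a sigmoid output trained with
# binary cross-entropy under Adam. Forward and backward passes are plain
# vectorized matrix algebra; the analytic gradients are checked against
# finite differences in the test suite.

#' Classifier configuration
#'
#' @param hidden_units LSTM hidden state size (default 64).
#' @param dense_units Units in the ReLU layer after the LSTM (default 32).
#' @param layers Number of LSTM layers (only 1 is supported).
#' @param learning_rate Adam step size (default 1e-3).
#' @param epochs Training epochs (default 50).
#' @param batch_size Minibatch size (default 128).
#' @param mask_value Sentinel marking missing timesteps (default -1).
#' @param seed Integer seed controlling initialization and shuffling; the
#'   same data + config + seed reproduce the same fit exactly.
#' @return A `model_config` list.
#' @export
model_config <- function(hidden_units = 64, dense_units = 32, layers = 1,
                         learning_rate = 1e-3, epochs = 50, batch_size = 128,
                         mask_value = -1, seed = 1L) {
  if (!is_count(hidden_units) || !is_count(dense_units) ||
      !is_count(epochs) || !is_count(batch_size))
    stopf("counts in model_config must be positive integers")
  if (layers != 1L) stopf("only a single LSTM layer is supported")
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stopf("learning_rate must be positive")
  structure(list(hidden_units = as.integer(hidden_units),
                 dense_units = as.integer(dense_units), layers = 1L,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), mask_value = mask_value,
                 seed = as.integer(seed)),
            class = "model_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(n_in, n_out) {
  r <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -r, r), n_in, n_out)
}

init_params <- function(n_features, config) {
  H <- config$hidden_units
  D <- config$dense_units
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1  # forget-gate bias: remember by default
  list(Wx = glorot(n_features, 4 * H), Wh = glorot(H, 4 * H), b = b,
       gamma = rep(1, H), beta = numeric(H),
       W1 = glorot(H, D), b1 = numeric(D),
       w2 = glorot(D, 1), b2 = 0)
}

LN_EPS <- 1e-5

# Forward pass over a batch. x: B x T x F array. Returns the probabilities
# and, if keep_cache, every intermediate needed by the backward pass.
lstm_forward <- function(params, x, mask_value, keep_cache = FALSE) {
  B <- dim(x)[1]; T_ <- dim(x)[2]
  H <- length(params$gamma)
  h <- matrix(0, B, H); c_ <- matrix(0, B, H)
  cache <- if (keep_cache) vector("list", T_)
  for (t in seq_len(T_)) {
    xt <- matrix(x[, t, ], nrow = B)
    m <- as.numeric(rowSums(xt != mask_value) > 0)  # 0 = fully masked step
    Z <- xt %*% params$Wx + h %*% params$Wh +
      matrix(params$b, B, 4 * H, byrow = TRUE)
    i <- sigmoid(Z[, 1:H, drop = FALSE])
    f <- sigmoid(Z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(Z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(Z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * c_ + i * g
    h_new <- o * tanh(c_new)
    if (keep_cache)
      cache[[t]] <- list(xt = xt, m = m, i = i, f = f, g = g, o = o,
                         c_prev = c_, h_prev = h, c_new = c_new)
    c_ <- m * c_new + (1 - m) * c_
    h <- m * h_new + (1 - m) * h
  }
  mu <- rowMeans(h)
  va <- rowMeans((h - mu)^2)
  inv <- 1 / sqrt(va + LN_EPS)
  hn <- (h - mu) * inv
  a <- sweep(sweep(hn, 2, params$gamma, `*`), 2, params$beta, `+`)
  pre1 <- sweep(a %*% params$W1, 2, params$b1, `+`)
  d <- pmax(pre1, 0)
  logit <- drop(d %*% params$w2) + params$b2
  p <- sigmoid(logit)
  out <- list(p = p)
  if (keep_cache)
    out <- c(out, list(cache = cache, h = h, hn = hn, inv = inv, a = a,
                       pre1 = pre1, d = d))
  out
}

# Backward pass for mean binary cross-entropy. Returns gradients with the
# same shapes as params.
lstm_backward <- function(params, x, y, fw, mask_value) {
  B <- dim(x)[1]; T_ <- dim(x)[2]
  H <- length(params$gamma)
  dlogit <- (fw$p - y) / B
  grads <- list(
    w2 = t(fw$d) %*% dlogit, b2 = sum(dlogit),
    W1 = NULL, b1 = NULL, gamma = NULL, beta = NULL,
    Wx = matrix(0, nrow(params$Wx), 4 * H),
    Wh = matrix(0, H, 4 * H), b = numeric(4 * H)
  )
  dd <- dlogit %*% t(params$w2)
  dpre1 <- dd * (fw$pre1 > 0)
  grads$W1 <- t(fw$a) %*% dpre1
  grads$b1 <- colSums(dpre1)
  da <- dpre1 %*% t(params$W1)
  grads$gamma <- colSums(da * fw$hn)
  grads$beta <- colSums(da)
  dhn <- sweep(da, 2, params$gamma, `*`)
  dh <- fw$inv * (dhn - rowMeans(dhn) - fw$hn * rowMeans(dhn * fw$hn))
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(T_))) {
    cc <- fw$cache[[t]]
    m <- cc$m
    dh_new <- m * dh; dh_skip <- (1 - m) * dh
    dc_new <- m * dc; dc_skip <- (1 - m) * dc
    tc <- tanh(cc$c_new)
    do_ <- dh_new * tc * cc$o * (1 - cc$o)
    dcn <- dc_new + dh_new * cc$o * (1 - tc^2)
    di <- dcn * cc$g * cc$i * (1 - cc$i)
    df <- dcn * cc$c_prev * cc$f * (1 - cc$f)
    dg <- dcn * cc$i * (1 - cc$g^2)
    dZ <- cbind(di, df, dg, do_)
    grads$Wx <- grads$Wx + t(cc$xt) %*% dZ
    grads$Wh <- grads$Wh + t(cc$h_prev) %*% dZ
    grads$b <- grads$b + colSums(dZ)
    dh <- dZ %*% t(params$Wh) + dh_skip
    dc <- dcn * cc$f + dc_skip
  }
  grads
}

bce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

#' Train the masked LSTM sepsis classifier
#'
#' Fits the sequence classifier on 4 x 21 feature windows with binary
#' cross-entropy under Adam. Timesteps whose features all equal the mask
#' sentinel contribute nothing to the recurrent update. Training is exactly
#' reproducible from the config seed.
#'
#' @param windows List of `feature_window`s (from [build_windows()] /
#'   [undersample_negatives()]) or a pre-stacked list from [stack_windows()].
#' @param config A [model_config()].
#' @return A `sepsis_model`: list with `params`, `config`, `n_features`,
#'   `history` (mean training loss per epoch).
#' @export
train_sepsis_model <- function(windows, config = model_config()) {
  data <- if (is.list(windows) && !is.null(windows$x)) windows
          else stack_windows(windows)
  x <- data$x; y <- data$y
  if (length(unique(y)) < 2L)
    stopf("training needs both classes present")
  n <- dim(x)[1]
  with_seed(config$seed, {
    params <- init_params(dim(x)[3], config)
    mstate <- lapply(params, function(p) p * 0)
    vstate <- lapply(params, function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        batch <- idx[start:min(start + config$batch_size - 1L, n)]
        xb <- x[batch, , , drop = FALSE]
        yb <- y[batch]
        fw <- lstm_forward(params, xb, config$mask_value, keep_cache = TRUE)
        loss <- bce_loss(fw$p, yb)
        if (!is.finite(loss)) stopf("non-finite training loss at epoch %d", epoch)
        losses <- c(losses, loss)
        grads <- lstm_backward(params, xb, yb, fw, config$mask_value)
        step <- step + 1L
        for (nm in names(params)) {
          mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * grads[[nm]]
          vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * grads[[nm]]^2
          mhat <- mstate[[nm]] / (1 - beta1^step)
          vhat <- vstate[[nm]] / (1 - beta2^step)
          params[[nm]] <- params[[nm]] -
            config$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      history[epoch] <- mean(losses)
    }
    structure(list(params = params, config = config,
                   n_features = dim(x)[3], history = history),
              class = "sepsis_model")
  })
}

#' @export
print.sepsis_model <- function(x, ...) {
  cat(sprintf(
    "<sepsis_model>  LSTM(%d) + LN + ReLU(%d), %d input features; %d epochs, final loss %.4f\n",
    x$config$hidden_units, x$config$dense_units, x$n_features,
    length(x$history), tail(x$history, 1)))
  invisible(x)
}

#' Predict the sepsis probability of one feature window
#'
#' @param model A trained `sepsis_model`.
#' @param window A `feature_window`, or a bare n_hours x n_features matrix.
#' @return A single probability in \[0, 1\]; deterministic for a fixed model.
#' @export
predict_window <- function(model, window) {
  mat <- if (inherits(window, "feature_window")) window$matrix else window
  if (!is.matrix(mat) || ncol(mat) != model$n_features)
    stopf("window shape mismatch: expected %d features", model$n_features)
  x <- array(mat, c(1, nrow(mat), ncol(mat)))
  unname(lstm_forward(model$params, x, model$config$mask_value)$p)
}

#' Hourly sepsis probability stream for one patient
#'
#' Slides the 4-hour window over a preprocessed record and scores every
#' window, yielding one probability per end hour (hours 4 through the stay
#' length).
#'
#' @param model A trained `sepsis_model`.
#' @param proc A `processed_record` from [preprocess_record()].
#' @param n_hours Window length (default 4).
#' @return Numeric probability vector with attribute `hours` (the ICULOS
#'   index of each prediction); length is stay - n_hours + 1.
#' @export
predict_patient <- function(model, proc, n_hours = 4) {
  windows <- build_windows(proc, n_hours = n_hours)
  data <- stack_windows(windows)
  p <- lstm_forward(model$params, data$x, model$config$mask_value)$p
  attr(p, "hours") <- as.integer(data$end_hour)
  p
}

#' Save / load a trained model archive
#'
#' @param model A `sepsis_model`.
#' @param path Archive file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "sepsis_model")) stopf("not a sepsis_model archive")
  model
}
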