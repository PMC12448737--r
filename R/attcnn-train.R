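# Vectorized 1-D CNN engine. Feature maps are B x p x C arrays (batch,
# position, channel); convolutions are expressed as k shifted matrix
# products so all heavy lifting goes through BLAS.

relu <- function(x) pmax(x, 0)

# out[, i, ] = A[, i + off, ], zero outside
shift_pos <- function(A, off) {
  if (off == 0L) return(A)
  d <- dim(A)
  out <- array(0, d)
  p <- d[2L]
  if (off > 0L) {
    out[, seq_len(p - off), ] <- A[, (1L + off):p, , drop = FALSE]
  } else {
    out[, (1L - off):p, ] <- A[, seq_len(p + off), , drop = FALSE]
  }
  out
}

conv1d_forward <- function(Ain, W, b) {
  d <- dim(Ain); B <- d[1L]; p <- d[2L]; cin <- d[3L]
  k <- dim(W)[1L]; cout <- dim(W)[3L]
  offs <- seq_len(k) - (k + 1L) %/% 2L
  pre <- matrix(0, B * p, cout)
  for (j in seq_len(k)) {
    M <- matrix(shift_pos(Ain, offs[j]), B * p, cin)
    pre <- pre + M %*% matrix(W[j, , ], cin, cout)
  }
  pre <- sweep(pre, 2L, b, "+")
  array(pre, c(B, p, cout))
}

conv1d_backward <- function(dPre, Ain, W) {
  d <- dim(Ain); B <- d[1L]; p <- d[2L]; cin <- d[3L]
  k <- dim(W)[1L]; cout <- dim(W)[3L]
  offs <- seq_len(k) - (k + 1L) %/% 2L
  dPre_mat <- matrix(dPre, B * p, cout)
  dW <- array(0, dim(W))
  dA <- array(0, d)
  for (j in seq_len(k)) {
    M <- matrix(shift_pos(Ain, offs[j]), B * p, cin)
    dW[j, , ] <- crossprod(M, dPre_mat)
    Tm <- dPre_mat %*% t(matrix(W[j, , ], cin, cout))
    dA <- dA + shift_pos(array(Tm, c(B, p, cin)), -offs[j])
  }
  list(dW = dW, db = colSums(dPre_mat), dA = dA)
}

# channel means over positions: B x p x C -> B x C
gap3 <- function(A) {
  d <- dim(A)
  rowSums(aperm(A, c(1L, 3L, 2L)), dims = 2L) / d[2L]
}

# spread B x C back over positions (each position gets dG / p)
gap3_backward <- function(dG, p) {
  d <- dim(dG)
  aperm(array(dG / p, c(d[1L], d[2L], p)), c(1L, 3L, 2L))
}

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

attcnn_init_params <- function(spec) {
  p <- spec$input_length
  k <- spec$kernel_size
  f1 <- spec$conv_filters[1L]; f2 <- spec$conv_filters[2L]
  att1 <- "after_conv1" %in% spec$attention_blocks
  att2 <- "after_conv2" %in% spec$attention_blocks
  feat_dim <- if (spec$head == "flatten") p * f2 else f2
  pr <- list(
    W1 = glorot(k, k * f1, c(k, 1L, f1)), b1 = numeric(f1),
    W2 = glorot(k * f1, k * f2, c(k, f1, f2)), b2 = numeric(f2)
  )
  if (att1) {
    pr$Wa1 <- glorot(f1, p, c(p, f1)); pr$ba1 <- numeric(p)
  }
  if (att2) {
    pr$Wa2 <- glorot(f2, p, c(p, f2)); pr$ba2 <- numeric(p)
  }
  if (spec$dense_units > 0L) {
    pr$Wd <- glorot(feat_dim, spec$dense_units, c(feat_dim, spec$dense_units))
    pr$bd <- numeric(spec$dense_units)
    out_in <- spec$dense_units
  } else {
    out_in <- feat_dim
  }
  pr$Wo <- glorot(out_in, 1L, c(out_in, 1L))
  pr$bo <- 0
  pr
}

attcnn_forward <- function(params, spec, X, drop_mask = NULL) {
  B <- nrow(X); p <- spec$input_length
  att1 <- "after_conv1" %in% spec$attention_blocks
  att2 <- "after_conv2" %in% spec$attention_blocks
  cc <- list()
  A0 <- array(X, c(B, p, 1L))
  cc$A0 <- A0
  cc$Pre1 <- conv1d_forward(A0, params$W1, params$b1)
  cc$H1 <- relu(cc$Pre1)
  H1in <- cc$H1
  if (att1) {
    cc$G1 <- gap3(cc$H1)
    cc$U1 <- sweep(cc$G1 %*% t(params$Wa1), 2L, params$ba1, "+")
    cc$Alpha1 <- row_softmax(cc$U1)
    H1in <- cc$H1 * as.vector(cc$Alpha1)
  }
  cc$H1in <- H1in
  cc$Pre2 <- conv1d_forward(H1in, params$W2, params$b2)
  cc$H2 <- relu(cc$Pre2)
  H2out <- cc$H2
  if (att2) {
    cc$G2 <- gap3(cc$H2)
    cc$U2 <- sweep(cc$G2 %*% t(params$Wa2), 2L, params$ba2, "+")
    cc$Alpha2 <- row_softmax(cc$U2)
    H2out <- cc$H2 * as.vector(cc$Alpha2)
  }
  cc$Feat <- if (spec$head == "flatten") matrix(H2out, B, p * spec$conv_filters[2L])
             else gap3(cc$H2)
  if (spec$dense_units > 0L) {
    cc$Zpre <- sweep(cc$Feat %*% params$Wd, 2L, params$bd, "+")
    cc$Z <- relu(cc$Zpre)
  } else {
    cc$Z <- cc$Feat
  }
  cc$Zd <- if (is.null(drop_mask)) cc$Z else cc$Z * drop_mask
  cc$logit <- as.vector(cc$Zd %*% params$Wo) + params$bo
  cc$yhat <- stats::plogis(cc$logit)
  cc
}

attcnn_backward <- function(params, spec, cc, y, drop_mask = NULL) {
  B <- length(y); p <- spec$input_length
  f2 <- spec$conv_filters[2L]
  att1 <- "after_conv1" %in% spec$attention_blocks
  att2 <- "after_conv2" %in% spec$attention_blocks
  gr <- list()
  dlogit <- (cc$yhat - y) / B
  gr$Wo <- crossprod(cc$Zd, matrix(dlogit, ncol = 1L))
  gr$bo <- sum(dlogit)
  dZd <- outer(dlogit, as.vector(params$Wo))
  dZ <- if (is.null(drop_mask)) dZd else dZd * drop_mask
  if (spec$dense_units > 0L) {
    dZpre <- dZ * (cc$Zpre > 0)
    gr$Wd <- crossprod(cc$Feat, dZpre)
    gr$bd <- colSums(dZpre)
    dFeat <- dZpre %*% t(params$Wd)
  } else {
    dFeat <- dZ
  }
  if (spec$head == "flatten") {
    dH2out <- array(dFeat, c(B, p, f2))
    if (att2) {
      dH2 <- dH2out * as.vector(cc$Alpha2)
      dAlpha2 <- matrix(rowSums(matrix(dH2out * cc$H2, B * p, f2)), B, p)
      dU2 <- cc$Alpha2 * (dAlpha2 - rowSums(cc$Alpha2 * dAlpha2))
      gr$Wa2 <- crossprod(dU2, cc$G2)
      gr$ba2 <- colSums(dU2)
      dG2 <- dU2 %*% params$Wa2
      dH2 <- dH2 + gap3_backward(dG2, p)
    } else {
      dH2 <- dH2out
    }
  } else {
    dH2 <- gap3_backward(dFeat, p)
  }
  dPre2 <- dH2 * (cc$Pre2 > 0)
  bk2 <- conv1d_backward(dPre2, cc$H1in, params$W2)
  gr$W2 <- bk2$dW; gr$b2 <- bk2$db
  dH1in <- bk2$dA
  if (att1) {
    dH1 <- dH1in * as.vector(cc$Alpha1)
    f1 <- spec$conv_filters[1L]
    dAlpha1 <- matrix(rowSums(matrix(dH1in * cc$H1, B * p, f1)), B, p)
    dU1 <- cc$Alpha1 * (dAlpha1 - rowSums(cc$Alpha1 * dAlpha1))
    gr$Wa1 <- crossprod(dU1, cc$G1)
    gr$ba1 <- colSums(dU1)
    dG1 <- dU1 %*% params$Wa1
    dH1 <- dH1 + gap3_backward(dG1, p)
  } else {
    dH1 <- dH1in
  }
  dPre1 <- dH1 * (cc$Pre1 > 0)
  bk1 <- conv1d_backward(dPre1, cc$A0, params$W1)
  gr$W1 <- bk1$dW; gr$b1 <- bk1$db
  gr
}

bce_loss <- function(yhat, y) {
  eps <- 1e-7
  yh <- pmin(pmax(yhat, eps), 1 - eps)
  -mean(y * log(yh) + (1 - y) * log(1 - yh))
}

#' Training configuration for the AttCNN
#'
#' Adam optimization of binary cross-entropy with mini-batches, a cap on
#' epochs, and early stopping on validation loss with best-weight restore.
#' An optional hyperparameter grid (learning rate, dropout rate, filter
#' pairs) can be searched by [crossval_evaluate()].
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Mini-batch size (default 16).
#' @param max_epochs Epoch cap (default 50).
#' @param patience Early-stopping patience in epochs (default 5; must be
#'   below `max_epochs`).
#' @param seed Integer seed driving all training randomness (weight
#'   initialization, shuffling, dropout).
#' @param grid Optional named list of candidate values:
#'   `learning_rate` (numeric vector), `dropout_rate` (numeric vector),
#'   `conv_filters` (list of integer pairs).
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 16L,
                         max_epochs = 50L, patience = 5L, seed = 1L,
                         grid = NULL) {
  stopifnot(batch_size >= 1L, patience < max_epochs, learning_rate > 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed), grid = grid),
            class = "train_config")
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train an AttCNN
#'
#' Minimizes binary cross-entropy with Adam on mini-batches. Training stops
#' when the validation loss has not improved for `patience` consecutive
#' epochs (or at `max_epochs`), and the weights of the best validation epoch
#' are restored. All randomness (initialization, shuffling, dropout) derives
#' from `cfg$seed`; the caller's RNG state is left untouched.
#'
#' @param spec An [attcnn_spec()] with `input_length == ncol(X_train)`.
#' @param cfg A [train_config()].
#' @param X_train,X_val Numeric matrices (samples x genes).
#' @param y_train,y_val Binary 0/1 label vectors; `y_train` must contain
#'   both classes.
#' @return An object of class `trained_attcnn`: `spec`, `params` (fitted
#'   weights), `history` (per-epoch train/validation loss), `best_epoch`.
#' @export
attcnn_train <- function(spec, cfg, X_train, y_train, X_val, y_val) {
  stopifnot(inherits(spec, "attcnn_spec"), inherits(cfg, "train_config"))
  X_train <- as.matrix(X_train); X_val <- as.matrix(X_val)
  if (ncol(X_train) != spec$input_length || ncol(X_val) != spec$input_length) {
    stop("input column count does not match spec$input_length")
  }
  y_train <- as.numeric(y_train); y_val <- as.numeric(y_val)
  if (length(unique(y_train)) < 2L) stop("training labels contain a single class")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(cfg$seed)

  params <- attcnn_init_params(spec)
  state <- list(m = lapply(params, function(x) x * 0),
                v = lapply(params, function(x) x * 0))
  n <- nrow(X_train)
  rate <- spec$dropout_rate
  drop_dim <- if (spec$dense_units > 0L) spec$dense_units
              else if (spec$head == "flatten") spec$input_length * spec$conv_filters[2L]
              else spec$conv_filters[2L]
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_val <- Inf; best_epoch <- 0L; best_params <- params
  wait <- 0L; t_step <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    idx <- sample.int(n)
    batch_losses <- numeric(0)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      bi <- idx[start:min(start + cfg$batch_size - 1L, n)]
      Xb <- X_train[bi, , drop = FALSE]
      yb <- y_train[bi]
      mask <- if (rate > 0) {
        matrix(stats::rbinom(length(bi) * drop_dim, 1L, 1 - rate) / (1 - rate),
               length(bi), drop_dim)
      } else NULL
      cc <- attcnn_forward(params, spec, Xb, drop_mask = mask)
      loss <- bce_loss(cc$yhat, yb)
      if (!is.finite(loss)) {
        stop(sprintf("non-finite training loss at epoch %d (lr=%g); try a smaller learning rate",
                     epoch, cfg$learning_rate))
      }
      batch_losses <- c(batch_losses, loss)
      gr <- attcnn_backward(params, spec, cc, yb, drop_mask = mask)
      t_step <- t_step + 1L
      upd <- adam_step(params, gr, state, cfg$learning_rate, t_step)
      params <- upd$params; state <- upd$state
    }
    val_hat <- attcnn_predict_params(params, spec, X_val)
    val_loss <- bce_loss(val_hat, y_val)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(batch_losses),
                                         val_loss = val_loss))
    if (val_loss < best_val - 1e-8) {
      best_val <- val_loss; best_epoch <- epoch
      best_params <- params
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  structure(list(spec = spec, params = best_params, history = history,
                 best_epoch = best_epoch, config = cfg),
            class = "trained_attcnn")
}

# inference in memory-bounded batches, dropout disabled
attcnn_predict_params <- function(params, spec, X, batch = 256L) {
  X <- as.matrix(X)
  out <- numeric(nrow(X))
  for (start in seq(1L, nrow(X), by = batch)) {
    bi <- start:min(start + batch - 1L, nrow(X))
    cc <- attcnn_forward(params, spec, X[bi, , drop = FALSE])
    out[bi] <- cc$yhat
  }
  eps <- 1e-7
  pmin(pmax(out, eps), 1 - eps)
}

#' Predict class probabilities from a trained AttCNN
#'
#' Deterministic inference (dropout disabled); outputs are clamped to the
#' open interval (0, 1).
#'
#' @param model A `trained_attcnn` from [attcnn_train()].
#' @param X Numeric matrix with `ncol(X) == spec$input_length`.
#' @return Probability vector, one entry per row of `X`.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "trained_attcnn"))
  X <- as.matrix(X)
  if (ncol(X) != model$spec$input_length) {
    stop("input column count does not match spec$input_length")
  }
  attcnn_predict_params(model$params, model$spec, X)
}

#' @export
print.trained_attcnn <- function(x, ...) {
  cat(sprintf("trained AttCNN (input length %d, %d params); best epoch %d of %d, val loss %.4f\n",
              x$spec$input_length, attcnn_n_params(x$spec), x$best_epoch,
              nrow(x$history), min(x$history$val_loss)))
  invisible(x)
}

# count of parameters actually instantiated in a weight list; must agree
# with the spec arithmetic of build_attcnn()
attcnn_count_weights <- function(params) {
  sum(vapply(params, length, integer(1)))
}
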