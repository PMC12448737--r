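ns <- asNamespace("attbiomarker")

test_that("the layer table reproduces the canonical parameter counts", {
  sp <- attcnn_spec(1000L)
  tbl <- build_attcnn(sp)
  expect_equal(sum(tbl$params), 8263593L)
  by_layer <- setNames(tbl$params, tbl$layer)
  expect_equal(unname(by_layer[c("conv1", "conv2", "attention2_dense",
                                 "dense", "output")]),
               c(128L, 6208L, 65000L, 8192128L, 129L))
  expect_equal(attcnn_n_params(attcnn_spec(100L)), 832293L)
  expect_error(attcnn_spec(2L), "input_length")
})

test_that("spec arithmetic equals the instantiated weight count for every variant", {
  two_att <- attcnn_spec(50L, attention_blocks = c("after_conv1", "after_conv2"))
  specs <- list(
    baseline = attcnn_spec(50L),
    two_att = two_att,
    WFAL = make_ablation("WFAL", two_att),
    WSAL = make_ablation("WSAL", two_att),
    RBAL = make_ablation("RBAL", two_att),
    RFCL = make_ablation("RFCL", attcnn_spec(50L)),
    plain = attcnn_spec(50L, attention_blocks = character(0), head = "gap"),
    wide = attcnn_spec(73L, conv_filters = c(16L, 32L), kernel_size = 5L)
  )
  set.seed(1)
  for (nm in names(specs)) {
    expect_identical(ns$attcnn_count_weights(ns$attcnn_init_params(specs[[nm]])),
                     attcnn_n_params(specs[[nm]]))
  }
})

test_that("ablation transformations follow the documented structure", {
  p <- 1000L
  two_att <- attcnn_spec(p, attention_blocks = c("after_conv1", "after_conv2"))
  base <- attcnn_spec(p)
  # single-attention ablations differ from the parent by one block's params
  expect_equal(attcnn_n_params(two_att) - attcnn_n_params(make_ablation("WFAL", two_att)),
               32L * p + p)
  expect_equal(attcnn_n_params(two_att) - attcnn_n_params(make_ablation("WSAL", two_att)),
               64L * p + p)
  rbal <- make_ablation("RBAL", two_att)
  expect_lt(attcnn_n_params(rbal), attcnn_n_params(base))
  expect_identical(make_ablation("RBAL", rbal), rbal)   # idempotent
  expect_lt(attcnn_n_params(make_ablation("RFCL", base)), attcnn_n_params(base))
  expect_error(make_ablation("WFAL", base), "post-conv-1")
  expect_error(make_ablation("nope", base))
  expect_equal(make_ablation("baseline", two_att)$attention_blocks, "after_conv2")
})

test_that("attention weights form a shift-invariant probability vector", {
  expect_equal(attention_weights(rep(3, 4)), rep(0.25, 4))
  expect_equal(attention_weights(c(0, log(2))), c(1 / 3, 2 / 3),
               tolerance = 1e-12)
  w <- attention_weights(c(1000, 0))
  expect_true(all(is.finite(w)))
  expect_equal(w[1], 1, tolerance = 1e-10)
  expect_error(attention_weights(c(1, NA)), "non-finite")
  set.seed(8)
  for (i in 1:20) {
    u <- rnorm(sample(2:30, 1), sd = 5)
    a <- attention_weights(u)
    expect_equal(sum(a), 1, tolerance = 1e-6)
    expect_true(all(a > 0))
    expect_equal(attention_weights(u + 17.3), a, tolerance = 1e-6)
  }
})

test_that("reweight-then-sum reproduces the attention context vector", {
  set.seed(9)
  for (i in 1:10) {
    np <- sample(2:8, 1); nc <- sample(1:5, 1)
    H <- matrix(rnorm(np * nc), np, nc)
    alpha <- attention_weights(rnorm(np))
    out <- context_reweight(H, alpha)
    # loop oracle for c = sum_i alpha_i h_i
    ctx <- rep(0, nc)
    for (j in seq_len(np)) ctx <- ctx + alpha[j] * H[j, ]
    expect_equal(colSums(out), ctx, tolerance = 1e-12)
  }
  H <- matrix(rnorm(15), 5, 3)
  expect_equal(colSums(context_reweight(H, rep(1 / 5, 5))),
               global_average_pool(H), tolerance = 1e-12)
  onehot <- c(0, 0, 1, 0, 0)
  expect_equal(colSums(context_reweight(H, onehot)), H[3, ])
  expect_error(context_reweight(H, rep(0.5, 2)), "shape mismatch")
})

test_that("global average pooling is the per-channel mean", {
  expect_equal(global_average_pool(matrix(c(1, 2, 3), ncol = 1)), c(2))
  expect_equal(global_average_pool(matrix(4, 7, 2)), c(4, 4))
  set.seed(10)
  H <- matrix(rnorm(14), 7, 2)
  manual <- c(sum(H[, 1]) / 7, sum(H[, 2]) / 7)
  expect_equal(unname(global_average_pool(H)), manual, tolerance = 1e-15)
})

test_that("analytic gradients match finite differences in every wiring", {
  grad_check <- function(spec, seed) {
    set.seed(seed)
    B <- 3L; p <- spec$input_length
    X <- matrix(rnorm(B * p), B, p)
    y <- c(0, 1, 1)
    params <- ns$attcnn_init_params(spec)
    loss_fn <- function(pr) ns$bce_loss(ns$attcnn_forward(pr, spec, X)$yhat, y)
    cc <- ns$attcnn_forward(params, spec, X)
    gr <- ns$attcnn_backward(params, spec, cc, y)
    worst <- 0
    for (nm in names(gr)) {
      for (i in sample(length(gr[[nm]]), min(4, length(gr[[nm]])))) {
        eps <- 1e-5
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
        worst <- max(worst, abs(num - gr[[nm]][i]) /
                       max(1e-6, abs(num) + abs(gr[[nm]][i])))
      }
    }
    worst
  }
  expect_lt(grad_check(attcnn_spec(15L), 21), 1e-4)
  expect_lt(grad_check(attcnn_spec(15L, attention_blocks = c("after_conv1",
                                                             "after_conv2")), 22), 1e-4)
  expect_lt(grad_check(attcnn_spec(15L, dense_units = 0L), 23), 1e-4)
  expect_lt(grad_check(attcnn_spec(15L, attention_blocks = character(0),
                                   head = "gap"), 24), 1e-4)
})

test_that("forcing uniform attention reduces the model to the unweighted map / n", {
  sp <- attcnn_spec(12L)
  set.seed(77)
  params <- ns$attcnn_init_params(sp)
  params$Wa2[] <- 0; params$ba2[] <- 0      # softmax of constants = uniform
  X <- matrix(rnorm(2 * 12), 2, 12)
  cc <- ns$attcnn_forward(params, sp, X)
  expect_equal(cc$Feat, matrix(cc$H2, 2, 12 * 64) / 12, tolerance = 1e-12)
})

test_that("training separates a separable problem, early-stops, and is seed-reproducible", {
  d <- make_planted(n = 40, p = 30, n_inf = 8, delta = 4, seed = 303)
  sp <- attcnn_spec(30L, conv_filters = c(8L, 16L), dense_units = 32L)
  cfg <- train_config(seed = 5L, batch_size = 8L)
  fit <- attcnn_train(sp, cfg, d$X, d$y, d$X, d$y)
  train_prob <- predict_proba(fit, d$X)
  expect_equal(unname(binary_metrics(d$y, train_prob)$acc), 1.0)
  expect_lte(nrow(fit$history), 50L)
  expect_lte(fit$best_epoch, nrow(fit$history))
  expect_gte(nrow(fit$history), 1L)
  # an unlearnable validation set plateaus and triggers early stopping
  set.seed(91)
  y_noise <- sample(d$y)
  fit_es <- attcnn_train(sp, cfg, d$X, d$y, d$X, y_noise)
  expect_lt(nrow(fit_es$history), 50L)
  expect_lt(fit_es$best_epoch, nrow(fit_es$history))
  fit2 <- attcnn_train(sp, cfg, d$X, d$y, d$X, d$y)
  expect_identical(predict_proba(fit2, d$X), train_prob)
  # different seed gives a different model
  fit3 <- attcnn_train(sp, train_config(seed = 6L, batch_size = 8L),
                       d$X, d$y, d$X, d$y)
  expect_false(identical(predict_proba(fit3, d$X), train_prob))
})

test_that("prediction is deterministic, bounded, and shape-checked", {
  d <- make_planted(n = 20, p = 10, n_inf = 2, delta = 2, seed = 70)
  sp <- attcnn_spec(10L, conv_filters = c(4L, 8L), dense_units = 8L)
  fit <- attcnn_train(sp, train_config(seed = 2L, max_epochs = 3L,
                                       patience = 2L, batch_size = 8L),
                      d$X, d$y, d$X, d$y)
  p1 <- predict_proba(fit, d$X)
  expect_identical(predict_proba(fit, d$X), p1)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_error(predict_proba(fit, d$X[, 1:5]), "input_length")
  expect_error(attcnn_train(sp, train_config(seed = 1L), d$X, rep(1, 20),
                            d$X, d$y), "single class")
})

test_that("the output unit is an exact sigmoid of its logit", {
  sp <- attcnn_spec(6L, conv_filters = c(2L, 3L), dense_units = 4L)
  set.seed(12)
  params <- ns$attcnn_init_params(sp)
  params$Wo[] <- 0; params$bo <- 0
  cc <- ns$attcnn_forward(params, sp, matrix(rnorm(12), 2, 6))
  expect_equal(cc$yhat, c(0.5, 0.5))   # sigma(0) = 1/2
})
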