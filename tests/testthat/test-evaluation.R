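test_that("stratified holdout preserves per-class proportions and is deterministic", {
  y <- rep(c(0L, 1L), each = 10)
  plan <- stratified_holdout(y, 0.2, seed = 11)
  expect_equal(sum(y[plan$test_indices] == 1), 2L)
  expect_equal(sum(y[plan$test_indices] == 0), 2L)
  expect_length(intersect(plan$train_indices, plan$test_indices), 0)
  plan2 <- stratified_holdout(y, 0.2, seed = 11)
  expect_identical(plan2$test_indices, plan$test_indices)
  # round-half-even: round(0.5 * 3) = 2 test samples per class, 1 in training
  p33 <- stratified_holdout(rep(c(0L, 1L), each = 3), 0.5, seed = 1)
  y33 <- rep(c(0L, 1L), each = 3)
  expect_equal(as.vector(table(y33[p33$test_indices])), c(2L, 2L))
  expect_equal(as.vector(table(y33[p33$train_indices])), c(1L, 1L))
  expect_error(stratified_holdout(rep(0L, 10), 0.2, seed = 1))
})

test_that("stratified k-fold partitions the training set with balanced classes", {
  y <- rep(c(0L, 1L), each = 25)
  folds <- stratified_kfold(y, k = 5, seed = 3)
  vals <- lapply(folds, `[[`, "validation")
  expect_setequal(unlist(vals), seq_along(y))
  expect_equal(sum(duplicated(unlist(vals))), 0L)
  for (f in folds) {
    expect_equal(sum(y[f$validation] == 1), 5L)
    expect_equal(sum(y[f$validation] == 0), 5L)
    expect_setequal(c(f$train, f$validation), seq_along(y))
  }
  expect_identical(stratified_kfold(y, k = 5, seed = 3), folds)
  expect_error(stratified_kfold(rep(c(0L, 1L), c(3, 30)), k = 5, seed = 1),
               "smaller than k")
})

test_that("per-fold class proportions never deviate by a full sample", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(30:120, 1)
    y <- sample(0:1, n, replace = TRUE, prob = c(0.6, 0.4))
    if (min(table(y)) < 10) next
    k <- sample(3:5, 1)
    folds <- stratified_kfold(y, k = k, seed = i)
    for (f in folds) {
      for (cl in 0:1) {
        expected <- sum(y == cl) / k
        expect_lt(abs(sum(y[f$validation] == cl) - expected), 1)
      }
    }
  }
})

test_that("thresholded metrics match the confusion-matrix hand example", {
  # TP=3 FP=1 FN=2 TN=4
  y <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  prob <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.6, 0.4, 0.3, 0.2, 0.1)
  mt <- binary_metrics(y, prob)
  expect_equal(mt$pre, 0.75)
  expect_equal(mt$rec, 0.6)
  expect_equal(mt$f1, 2 / 3)
  expect_equal(mt$acc, 0.7)
  perfect <- binary_metrics(y, y)
  expect_equal(unlist(perfect), c(auc = 1, acc = 1, f1 = 1, pre = 1, rec = 1))
})

test_that("probability ties at the threshold predict positive", {
  y <- c(1, 1, 0, 0)
  mt <- binary_metrics(y, rep(0.5, 4))
  expect_equal(mt$acc, 0.5)   # everything predicted positive
  expect_equal(mt$rec, 1)
  expect_equal(mt$pre, 0.5)
  expect_warning(single <- binary_metrics(c(1, 1), c(0.2, 0.9)), "AUC undefined")
  expect_true(is.na(single$auc))
  expect_equal(single$acc, 0.5)
})

test_that("rank-based AUC equals exhaustive pair counting", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.5, 0.1)), 0.75)
  expect_equal(roc_auc(c(1, 0), c(5, 1)), 1)
  expect_equal(roc_auc(c(1, 1, 0, 0), rep(0.3, 4)), 0.5)
  set.seed(77)
  for (i in 1:30) {
    n <- sample(4:50, 1)
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    expect_equal(roc_auc(y, s), auc_paircount(y, s), tolerance = 1e-12)
  }
  expect_error(roc_auc(rep(1, 4), runif(4)), "both classes")
})

test_that("delong self-comparison and antisymmetry hold exactly", {
  set.seed(5)
  y <- rep(c(0L, 1L), each = 15)
  s <- rnorm(30) + y
  self <- delong_test(y, s, s)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)
  expect_equal(self$delta_auc, 0)
  s2 <- rnorm(30) + 0.5 * y
  ab <- delong_test(y, s, s2)
  ba <- delong_test(y, s2, s)
  expect_equal(ab$delta_auc, -ba$delta_auc)
  expect_equal(ab$z^2, ba$z^2, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
})

test_that("delong agrees with an independent implementation (pROC)", {
  skip_if_not_installed("pROC")
  set.seed(6)
  for (i in 1:5) {
    y <- rep(c(0L, 1L), each = 20)
    base <- rnorm(40) + y
    a <- base + rnorm(40, sd = 0.5)
    b <- base + rnorm(40, sd = 0.8)
    got <- delong_test(y, a, b)
    ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                          pROC::roc(y, b, quiet = TRUE), method = "delong")
    expect_equal(got$z, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(got$p, ref$p.value, tolerance = 1e-8)
  }
})

test_that("delong p-value is consistent with a bootstrap null on a small case", {
  set.seed(30)
  n <- 30
  y <- rep(c(0L, 1L), each = n / 2)
  base <- rnorm(n) + 0.8 * y
  a <- base + rnorm(n, sd = 0.6)
  b <- base + rnorm(n, sd = 0.6)
  got <- delong_test(y, a, b)
  # stratified-bootstrap distribution of dAUC under resampling
  reps <- 2000
  obs <- got$delta_auc
  boot <- replicate(reps, {
    idx <- c(sample(which(y == 0), n / 2, TRUE), sample(which(y == 1), n / 2, TRUE))
    roc_auc(y[idx], a[idx]) - roc_auc(y[idx], b[idx])
  })
  boot_p <- 2 * min(mean(boot - mean(boot) >= abs(obs)),
                    mean(boot - mean(boot) <= -abs(obs)))
  expect_lt(abs(got$p - min(boot_p, 1)), 0.1)
})

test_that("a deterministic stub classifier reproduces manual per-fold metrics", {
  set.seed(50)
  n <- 60; p <- 4
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1] <- X[, 1] + y
  m <- tiny_lem(X, y)
  stub <- classifier_adapter(
    "stub",
    fit = function(X, y, seed) range(X[, 1]),
    predict = function(fit, X) (X[, 1] - fit[1]) / (fit[2] - fit[1] + 1e-12))
  plan <- make_split_plan(y, test_fraction = 0.2, k = 3, seed = 4)
  rep <- crossval_evaluate(stub, m, plan)
  for (fi in 1:3) {
    fold <- plan$folds[[fi]]
    rng <- range(X[fold$train, 1])
    prob <- (X[fold$validation, 1] - rng[1]) / (rng[2] - rng[1] + 1e-12)
    manual <- binary_metrics(y[fold$validation], prob)
    expect_equal(rep$per_fold[fi, -1], manual, ignore_attr = TRUE)
  }
  expect_equal(nrow(rep$per_fold), 3L)
  expect_equal(rep$aggregate$mean[rep$aggregate$metric == "acc"],
               mean(rep$per_fold$acc))
})

test_that("label-independent scores give chance-level CV AUC", {
  set.seed(60)
  n <- 200
  y <- rep(c(0L, 1L), each = n / 2)
  m <- tiny_lem(matrix(rnorm(n * 3), n, 3), y)
  noise <- classifier_adapter(
    "noise",
    fit = function(X, y, seed) seed,
    predict = function(fit, X) {
      set.seed(fit); runif(nrow(X))
    })
  plan <- make_split_plan(y, k = 5, seed = 8)
  rep <- crossval_evaluate(noise, m, plan)
  cv_auc <- rep$aggregate$mean[rep$aggregate$metric == "auc"]
  expect_gte(cv_auc, 0.35)
  expect_lte(cv_auc, 0.65)
})

test_that("classifier comparison shares splits and self-comparison gives p = 1", {
  set.seed(70)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 3), n, 3)
  X[, 2] <- X[, 2] + 1.2 * y
  m <- tiny_lem(X, y)
  stub <- function(nm) classifier_adapter(
    nm,
    fit = function(X, y, seed) NULL,
    predict = function(fit, X) plogis(X[, 2]))
  plan <- make_split_plan(y, k = 3, seed = 9)
  cmp <- compare_classifiers(m, plan, list(a = stub("a"), b = stub("b")))
  expect_equal(nrow(cmp$summary), 2L)
  expect_equal(cmp$delong$p, 1)
  expect_equal(cmp$delong$delta_auc, 0)
  # single classifier degenerates to crossval_evaluate
  cmp1 <- compare_classifiers(m, plan, list(a = stub("a")))
  solo <- crossval_evaluate(stub("a"), m, plan)
  expect_equal(cmp1$reports$a$test, solo$test)
  expect_null(cmp1$delong)
  # a failing classifier is recorded while others continue
  bad <- classifier_adapter("bad", fit = function(X, y, seed) stop("boom"),
                            predict = function(fit, X) NULL)
  cmp2 <- compare_classifiers(m, plan, list(a = stub("a"), bad = bad))
  expect_s3_class(cmp2$reports$bad, "classifier_failure")
  expect_equal(nrow(cmp2$summary), 1L)
})
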