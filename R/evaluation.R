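#' Stratified train/test holdout split
#'
#' Shuffles each class independently with the given seed and moves
#' `round(test_fraction * class size)` samples of each class (round-half-even,
#' R's default rounding) into the test partition.
#'
#' @param labels Binary 0/1 vector.
#' @param test_fraction Fraction held out (default 0.2).
#' @param seed Integer seed.
#' @return A list of class `split_plan`: `train_indices`, `test_indices`,
#'   `seed`, `test_fraction` (folds are added by [stratified_kfold()] or
#'   [make_split_plan()]).
#' @export
stratified_holdout <- function(labels, test_fraction = 0.2, seed) {
  labels <- as.integer(labels)
  stopifnot(test_fraction > 0, test_fraction < 1)
  classes <- sort(unique(labels))
  stopifnot(length(classes) == 2L)
  test_idx <- integer(0)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  for (cl in classes) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) stop("class ", cl, " has fewer than 2 samples")
    n_test <- round(test_fraction * length(idx))
    if (n_test < 1L || n_test >= length(idx)) {
      stop("class ", cl, " too small to appear in both partitions at fraction ",
           test_fraction)
    }
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  test_idx <- sort(test_idx)
  structure(list(train_indices = setdiff(seq_along(labels), test_idx),
                 test_indices = test_idx, folds = NULL,
                 seed = as.integer(seed), test_fraction = test_fraction),
            class = "split_plan")
}

#' Stratified k-fold assignment
#'
#' Partitions the given indices into k folds with per-fold class counts
#' differing by at most one, by shuffling within class and dealing
#' round-robin.
#'
#' @param labels Binary 0/1 vector over all samples.
#' @param k Number of folds (default 5); every class must have >= k samples
#'   among `indices`.
#' @param seed Integer seed.
#' @param indices Sample indices to partition (default: all).
#' @return List of k elements, each `list(train = ..., validation = ...)`.
#' @export
stratified_kfold <- function(labels, k = 5L, seed, indices = seq_along(labels)) {
  labels <- as.integer(labels)
  classes <- sort(unique(labels[indices]))
  stopifnot(length(classes) == 2L, k >= 2L)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  fold_of <- integer(length(labels))
  for (cl in classes) {
    idx <- indices[labels[indices] == cl]
    if (length(idx) < k) stop("class ", cl, " smaller than k = ", k)
    idx <- sample(idx)
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) {
    val <- indices[fold_of[indices] == f]
    list(train = setdiff(indices, val), validation = val)
  })
}

#' Build a complete resampling plan (holdout + folds on the training part)
#'
#' @param labels Binary 0/1 vector.
#' @param test_fraction Held-out fraction (default 0.2).
#' @param k Folds on the training partition (default 5).
#' @param seed Integer seed.
#' @return A `split_plan` with `folds` filled in.
#' @export
make_split_plan <- function(labels, test_fraction = 0.2, k = 5L, seed) {
  plan <- stratified_holdout(labels, test_fraction, seed)
  plan$folds <- stratified_kfold(labels, k = k, seed = seed + 1L,
                                 indices = plan$train_indices)
  plan
}

#' Threshold-free AUC via the rank (Mann-Whitney U) statistic
#'
#' `AUC = U / (n1 * n0)` with midranks, i.e. tied case/control score pairs
#' count one half; identical to trapezoidal integration of the ROC curve.
#'
#' @param y_true Binary 0/1 vector containing both classes.
#' @param scores Real-valued classifier scores (higher = more case-like).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(scores)) stop("length mismatch")
  n1 <- sum(y_true == 1L); n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Thresholded classification metrics plus AUC
#'
#' Accuracy, precision, recall and F1 from the confusion matrix at
#' `y_prob >= threshold` (ties predict positive; positive class = 1),
#' plus threshold-free AUC. Precision is 0 when nothing is predicted
#' positive; F1 is 0 when precision + recall is 0. With single-class
#' `y_true` the AUC is `NA` with a warning while the thresholded metrics
#' are still returned.
#'
#' @param y_true Binary 0/1 vector.
#' @param y_prob Probability (or score) vector.
#' @param threshold Decision threshold (default 0.5).
#' @return One-row `data.frame` with columns `auc`, `acc`, `f1`, `pre`,
#'   `rec`.
#' @export
binary_metrics <- function(y_true, y_prob, threshold = 0.5) {
  y_true <- as.integer(y_true)
  stopifnot(length(y_true) == length(y_prob))
  pred <- as.integer(y_prob >= threshold)
  tp <- sum(pred == 1L & y_true == 1L)
  fp <- sum(pred == 1L & y_true == 0L)
  fn <- sum(pred == 0L & y_true == 1L)
  tn <- sum(pred == 0L & y_true == 0L)
  acc <- (tp + tn) / length(y_true)
  pre <- if (tp + fp > 0L) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0
  auc <- if (length(unique(y_true)) < 2L) {
    warning("AUC undefined for single-class y_true")
    NA_real_
  } else roc_auc(y_true, y_prob)
  data.frame(auc = auc, acc = acc, f1 = f1, pre = pre, rec = rec)
}

# midrank structural components (one model): list(auc, v10 (length n1), v01)
.delong_components <- function(y_true, scores) {
  pos <- scores[y_true == 1L]
  neg <- scores[y_true == 0L]
  n1 <- length(pos); n0 <- length(neg)
  all_r <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (all_r[seq_len(n1)] - r_pos) / n0
  v01 <- 1 - (all_r[n1 + seq_len(n0)] - r_neg) / n1
  list(auc = sum(v10) / n1, v10 = v10, v01 = v01)
}

#' DeLong test for two correlated AUCs
#'
#' Nonparametric comparison of the AUCs of two score vectors computed on the
#' same samples, using the structural-component (midrank) estimator of the
#' covariance of the paired AUCs; `z = dAUC / sqrt(var)` with a two-sided
#' normal p-value.
#'
#' @param y_true Binary 0/1 vector (both classes present).
#' @param scores_a,scores_b Score vectors of the two models on the same
#'   samples.
#' @return A list of class `delong_result`: `delta_auc` (AUC_a - AUC_b),
#'   `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_test <- function(y_true, scores_a, scores_b) {
  y_true <- as.integer(y_true)
  stopifnot(length(y_true) == length(scores_a),
            length(y_true) == length(scores_b))
  if (length(unique(y_true)) < 2L) stop("both classes required")
  ca <- .delong_components(y_true, scores_a)
  cb <- .delong_components(y_true, scores_b)
  n1 <- length(ca$v10); n0 <- length(ca$v01)
  delta <- ca$auc - cb$auc
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  if (v <= 0) {
    if (abs(delta) < 1e-12) {
      z <- 0; p <- 1
    } else {
      stop("degenerate variance of the AUC difference")
    }
  } else {
    z <- delta / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(delta_auc = delta, auc_a = ca$auc, auc_b = cb$auc,
                 z = z, p = p),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong test: dAUC = %.4f (%.4f vs %.4f), Z = %.3f, p = %.4g\n",
              x$delta_auc, x$auc_a, x$auc_b, x$z, x$p))
  invisible(x)
}

#' Classifier adapter
#'
#' Uniform interface used by [crossval_evaluate()] and
#' [compare_classifiers()]: a `fit(X, y, seed)` closure returning a fitted
#' object and a `predict(fit, X)` closure returning case probabilities.
#'
#' @param name Classifier label.
#' @param fit Function `(X, y, seed) -> fitted object`.
#' @param predict Function `(fitted, X) -> probability vector`.
#' @return A list of class `classifier_adapter`.
#' @export
classifier_adapter <- function(name, fit, predict) {
  structure(list(name = name, fit = fit, predict = predict),
            class = "classifier_adapter")
}

#' AttCNN classifier adapter
#'
#' Wraps [attcnn_train()] for the resampling harness. Inside `fit`, a
#' stratified 15% of the provided training samples is carved out as the
#' early-stopping validation set. When `spec` is `NULL` it is built per fit
#' with `input_length = ncol(X)` and the supplied architecture arguments.
#'
#' @param spec Optional fixed [attcnn_spec()].
#' @param cfg A [train_config()]; its `grid` (if any) is searched by
#'   [crossval_evaluate()], not here.
#' @param ... Arguments passed to [attcnn_spec()] when `spec` is `NULL`.
#' @return A `classifier_adapter`.
#' @export
attcnn_classifier <- function(spec = NULL, cfg = train_config(), ...) {
  spec_args <- list(...)
  classifier_adapter(
    name = "attcnn",
    fit = function(X, y, seed) {
      sp <- if (is.null(spec)) {
        do.call(attcnn_spec, c(list(input_length = ncol(X)), spec_args))
      } else spec
      inner <- stratified_holdout(y, test_fraction = 0.15, seed = seed)
      cfg$seed <- seed
      attcnn_train(sp, cfg,
                   X[inner$train_indices, , drop = FALSE], y[inner$train_indices],
                   X[inner$test_indices, , drop = FALSE], y[inner$test_indices])
    },
    predict = function(fit, X) predict_proba(fit, X)
  )
}

# apply a train_config grid combo onto (spec_args, cfg)
.expand_grid_combos <- function(cfg) {
  g <- cfg$grid
  if (is.null(g)) return(list(list(cfg = cfg, spec_override = list())))
  lr <- if (is.null(g$learning_rate)) cfg$learning_rate else g$learning_rate
  dr <- if (is.null(g$dropout_rate)) NA else g$dropout_rate
  fl <- if (is.null(g$conv_filters)) list(NULL) else g$conv_filters
  combos <- list()
  for (l in lr) for (d in dr) for (f in fl) {
    c2 <- cfg; c2$learning_rate <- l; c2$grid <- NULL
    ov <- list()
    if (!is.na(d)) ov$dropout_rate <- d
    if (!is.null(f)) ov$conv_filters <- f
    combos[[length(combos) + 1L]] <- list(cfg = c2, spec_override = ov)
  }
  combos
}

#' Cross-validated evaluation with a final held-out test
#'
#' For each fold of the plan, fits the classifier on the fold-train part and
#' scores the fold-validation part; then refits on the full training
#' partition and reports metrics on the held-out test partition (the
#' headline numbers). When the adapter is an AttCNN adapter whose
#' [train_config()] carries a `grid`, every hyperparameter combination is
#' cross-validated and the combination with the best mean fold accuracy
#' (AUC tie-break) is refit.
#'
#' @param classifier A `classifier_adapter` (e.g. [attcnn_classifier()]).
#' @param m A [labeled_expression_matrix()].
#' @param plan A `split_plan` from [make_split_plan()] built on `m`'s
#'   labels. `plan$folds` may be `NULL`, in which case only the held-out
#'   evaluation is run.
#' @return An object of class `eval_report`: `per_fold` (data.frame of fold
#'   metrics), `aggregate` (mean and sd), `test` (held-out metrics),
#'   `test_scores`, `test_indices`.
#' @export
crossval_evaluate <- function(classifier, m, plan) {
  stopifnot(inherits(classifier, "classifier_adapter"), inherits(m, "lem"),
            inherits(plan, "split_plan"))
  X <- m$values; y <- m$labels
  run_cv <- function(cls, seed_off = 0L) {
    rows <- lapply(seq_along(plan$folds), function(fi) {
      fold <- plan$folds[[fi]]
      fit <- tryCatch(
        cls$fit(X[fold$train, , drop = FALSE], y[fold$train],
                seed = plan$seed + 100L * fi + seed_off),
        error = function(e) stop("fold ", fi, ": ", conditionMessage(e)))
      prob <- cls$predict(fit, X[fold$validation, , drop = FALSE])
      cbind(fold = fi, binary_metrics(y[fold$validation], prob))
    })
    do.call(rbind, rows)
  }
  is_attcnn_grid <- identical(classifier$name, "attcnn") &&
    !is.null(environment(classifier$fit)$cfg$grid)
  per_fold <- NULL
  final_classifier <- classifier
  if (is_attcnn_grid && !is.null(plan$folds)) {
    cfg0 <- environment(classifier$fit)$cfg
    spec_args0 <- environment(classifier$fit)$spec_args
    combos <- .expand_grid_combos(cfg0)
    best <- NULL
    for (ci in seq_along(combos)) {
      cmb <- combos[[ci]]
      cand <- do.call(attcnn_classifier,
                      c(list(spec = NULL, cfg = cmb$cfg),
                        utils::modifyList(spec_args0, cmb$spec_override)))
      pf <- run_cv(cand, seed_off = 0L)
      key <- c(mean(pf$acc), mean(pf$auc))
      if (is.null(best) || key[1] > best$key[1] ||
          (key[1] == best$key[1] && key[2] > best$key[2])) {
        best <- list(key = key, classifier = cand, per_fold = pf)
      }
    }
    per_fold <- best$per_fold
    final_classifier <- best$classifier
  } else if (!is.null(plan$folds)) {
    per_fold <- run_cv(classifier)
  }
  fit <- final_classifier$fit(X[plan$train_indices, , drop = FALSE],
                              y[plan$train_indices], seed = plan$seed)
  test_scores <- final_classifier$predict(fit, X[plan$test_indices, , drop = FALSE])
  test <- binary_metrics(y[plan$test_indices], test_scores)
  aggregate <- if (!is.null(per_fold)) {
    data.frame(metric = c("auc", "acc", "f1", "pre", "rec"),
               mean = vapply(c("auc", "acc", "f1", "pre", "rec"),
                             function(k) mean(per_fold[[k]]), numeric(1)),
               sd = vapply(c("auc", "acc", "f1", "pre", "rec"),
                           function(k) stats::sd(per_fold[[k]]), numeric(1)))
  } else NULL
  structure(list(classifier = final_classifier$name, per_fold = per_fold,
                 aggregate = aggregate, test = test,
                 test_scores = test_scores,
                 test_indices = plan$test_indices, model = fit),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("evaluation of '%s'\n", x$classifier))
  if (!is.null(x$aggregate)) {
    cat(sprintf("  CV mean: AUC %.4f  ACC %.4f  F1 %.4f\n",
                x$aggregate$mean[1], x$aggregate$mean[2], x$aggregate$mean[3]))
  }
  cat(sprintf("  held-out test: AUC %.4f  ACC %.4f  F1 %.4f  PRE %.4f  REC %.4f\n",
              x$test$auc, x$test$acc, x$test$f1, x$test$pre, x$test$rec))
  invisible(x)
}

#' Compare several classifiers on identical splits
#'
#' Evaluates every adapter with [crossval_evaluate()] on the same plan, then
#' runs the DeLong test on every pair of held-out test score vectors.
#' A failing classifier is recorded with its error and the others continue.
#'
#' @param m A [labeled_expression_matrix()].
#' @param plan A `split_plan`.
#' @param classifiers Named list of `classifier_adapter`s.
#' @return List of class `classifier_comparison`: `reports` (named list of
#'   `eval_report` or error messages), `summary` (one row per classifier),
#'   `delong` (pairwise data.frame `model_a`, `model_b`, `delta_auc`, `z`,
#'   `p`).
#' @export
compare_classifiers <- function(m, plan, classifiers) {
  stopifnot(length(classifiers) >= 1L)
  if (is.null(names(classifiers))) {
    names(classifiers) <- vapply(classifiers, `[[`, character(1), "name")
  }
  reports <- lapply(classifiers, function(cls) {
    tryCatch(crossval_evaluate(cls, m, plan),
             error = function(e) structure(conditionMessage(e),
                                           class = "classifier_failure"))
  })
  ok <- !vapply(reports, inherits, logical(1), "classifier_failure")
  summary <- do.call(rbind, lapply(names(reports)[ok], function(nm) {
    cbind(model = nm, reports[[nm]]$test)
  }))
  y_test <- m$labels[plan$test_indices]
  pairs <- if (sum(ok) >= 2L) utils::combn(names(reports)[ok], 2L) else NULL
  delong <- if (!is.null(pairs)) {
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      dl <- delong_test(y_test, reports[[a]]$test_scores,
                        reports[[b]]$test_scores)
      data.frame(model_a = a, model_b = b, delta_auc = dl$delta_auc,
                 z = dl$z, p = dl$p)
    }))
  } else NULL
  structure(list(reports = reports, summary = summary, delong = delong),
            class = "classifier_comparison")
}

#' Support-vector-machine comparator (RBF kernel, via e1071)
#'
#' @param ... Passed to [e1071::svm()].
#' @return A `classifier_adapter`.
#' @export
svm_classifier <- function(...) {
  if (!requireNamespace("e1071", quietly = TRUE)) {
    stop("the 'e1071' package is required for the SVM comparator")
  }
  args <- list(...)
  classifier_adapter(
    name = "svm",
    fit = function(X, y, seed) {
      set.seed(seed)
      do.call(e1071::svm,
              c(list(x = X, y = factor(y, levels = c(0, 1)),
                     probability = TRUE), args))
    },
    predict = function(fit, X) {
      pr <- attr(stats::predict(fit, X, probability = TRUE), "probabilities")
      pr[, "1"]
    }
  )
}

#' Gradient-boosting comparator (via xgboost)
#'
#' @param nrounds Boosting rounds (default 100).
#' @param ... Passed to [xgboost::xgboost()] params.
#' @return A `classifier_adapter`.
#' @export
xgboost_classifier <- function(nrounds = 100L, ...) {
  if (!requireNamespace("xgboost", quietly = TRUE)) {
    stop("the 'xgboost' package is required for the boosting comparator")
  }
  args <- list(...)
  classifier_adapter(
    name = "xgboost",
    fit = function(X, y, seed) {
      set.seed(seed)
      xgboost::xgboost(data = X, label = y, nrounds = nrounds,
                       objective = "binary:logistic", verbose = 0,
                       nthread = 1L, params = args)
    },
    predict = function(fit, X) stats::predict(fit, X)
  )
}

#' Plain-CNN comparator
#'
#' The AttCNN with all attention blocks removed and global average pooling
#' feeding the dense head directly: `conv -> conv -> GAP -> dense(128) ->
#' dropout -> sigmoid`.
#'
#' @param cfg A [train_config()].
#' @param ... Passed to [attcnn_spec()] (besides `attention_blocks`/`head`).
#' @return A `classifier_adapter`.
#' @export
plain_cnn_classifier <- function(cfg = train_config(), ...) {
  ad <- attcnn_classifier(spec = NULL, cfg = cfg,
                          attention_blocks = character(0), head = "gap", ...)
  ad$name <- "cnn"
  ad
}
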