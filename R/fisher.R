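#' Per-gene Fisher scores
#'
#' Round-1 filter criterion. For gene i with classes x = 1..L the score is
#'
#' \deqn{f(i) = \frac{\sum_x q_x (\mu_i^x - \mu_i)^2}{\sum_x q_x (\sigma_i^x)^2}}
#'
#' where \eqn{\mu_i^x}, \eqn{\sigma_i^x} are the class mean and *population*
#' (divide-by-n) standard deviation, \eqn{\mu_i} the grand mean, and
#' \eqn{q_x} the class size. Population standard deviations make the score of
#' a single gene equal the trace-ratio criterion of
#' [fisher_trace_criterion()], whose scatter matrices are unnormalized sums.
#'
#' A zero denominator with positive numerator yields `Inf` (flagged); a gene
#' with no variance and no separation scores 0.
#'
#' @param m A [labeled_expression_matrix()] with >= 2 classes, each of
#'   size >= 2.
#' @return An object of class `fisher_ranking`: list with `scores` (named,
#'   per gene), `order` (gene indices by descending score, ties by ascending
#'   index), `class_stats`, `n_classes`, and `infinite` (logical flags).
#' @export
fisher_scores <- function(m) {
  stopifnot(inherits(m, "lem"))
  classes <- sort(unique(m$labels))
  if (length(classes) < 2L) stop("labels contain a single class")
  q_x <- vapply(classes, function(cl) sum(m$labels == cl), integer(1))
  if (any(q_x < 2L)) stop("each class needs at least 2 samples")
  p <- ncol(m$values)
  mu_all <- colMeans(m$values)
  num <- den <- numeric(p)
  class_stats <- list()
  for (ci in seq_along(classes)) {
    xc <- m$values[m$labels == classes[ci], , drop = FALSE]
    mu_c <- colMeans(xc)
    var_c <- colMeans(sweep(xc, 2L, mu_c)^2)   # population variance
    num <- num + q_x[ci] * (mu_c - mu_all)^2
    den <- den + q_x[ci] * var_c
    class_stats[[as.character(classes[ci])]] <-
      list(mean = mu_c, sd = sqrt(var_c), q = q_x[ci])
  }
  scores <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  names(scores) <- m$gene_ids
  ord <- order(-scores, seq_len(p))
  structure(list(scores = scores, order = ord, class_stats = class_stats,
                 n_classes = length(classes),
                 infinite = is.infinite(scores)),
            class = "fisher_ranking")
}

#' @export
print.fisher_ranking <- function(x, ...) {
  cat(sprintf("Fisher ranking of %d genes (%d classes); top gene: %s (%.4g)\n",
              length(x$scores), x$n_classes,
              names(x$scores)[x$order[1L]], x$scores[x$order[1L]]))
  invisible(x)
}

#' Trace-form Fisher criterion of a gene subset
#'
#' Subset-level criterion \eqn{f(S') = tr(M_b)/tr(M_w)} on the reduced
#' matrix, with the between-class scatter
#' \eqn{M_b = \sum_x q_x (\bar\mu_x - \bar\mu)(\bar\mu_x - \bar\mu)^T} and the
#' standard within-class scatter
#' \eqn{M_w = \sum_j (z_j - \bar\mu_{class(j)})(z_j - \bar\mu_{class(j)})^T}
#' (deviations from each sample's own class mean, i.e. the pooled
#' unnormalized scatter).
#'
#' @param m A [labeled_expression_matrix()].
#' @param gene_subset Integer indices or gene ids of the subset columns.
#' @return Scalar trace ratio.
#' @export
fisher_trace_criterion <- function(m, gene_subset) {
  stopifnot(inherits(m, "lem"), length(gene_subset) >= 1L)
  z <- m$values[, gene_subset, drop = FALSE]
  classes <- sort(unique(m$labels))
  if (length(classes) < 2L) stop("labels contain a single class")
  mu <- colMeans(z)
  tr_b <- 0; tr_w <- 0
  for (cl in classes) {
    zc <- z[m$labels == cl, , drop = FALSE]
    mu_c <- colMeans(zc)
    tr_b <- tr_b + nrow(zc) * sum((mu_c - mu)^2)
    tr_w <- tr_w + sum(sweep(zc, 2L, mu_c)^2)
  }
  if (tr_w == 0) stop("degenerate within-class scatter")
  tr_b / tr_w
}

#' Detect the deflection (knee) point of a sorted score curve
#'
#' Automates the visual "deflection point" read off a descending score curve:
#' both axes are min-max normalized, and the returned index maximizes the
#' perpendicular distance from the curve to the chord joining its endpoints
#' (Kneedle-style). Ties break to the smallest index. A curve with no knee
#' (all distances ~ 0, e.g. constant or exactly linear decay) returns `n`
#' with a warning, i.e. "keep everything".
#'
#' @param sorted_scores Non-increasing numeric vector, length >= 3.
#' @return Integer index `k`; genes ranked `1..k` form the recommended
#'   subset.
#' @export
detect_deflection <- function(sorted_scores) {
  s <- as.numeric(sorted_scores)
  n <- length(s)
  stopifnot(n >= 3L)
  if (any(diff(s) > 1e-9 * max(abs(s), 1))) {
    stop("scores must be sorted non-increasingly")
  }
  rng <- max(s) - min(s)
  if (rng == 0) {
    warning("all scores equal; no deflection point")
    return(n)
  }
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - min(s)) / rng
  # chord from (x1, y1)=(0,1) to (xn, yn)=(1,0); distance ~ |x + y - 1|
  d <- abs(x + y - 1) / sqrt(2)
  d[c(1L, n)] <- -Inf   # interior points only
  if (max(d) < 1e-9) {
    warning("score curve has no deflection point (near-linear decay)")
    return(n)
  }
  which.max(d)
}

#' Take the top-k genes of a Fisher ranking
#'
#' Reduces the matrix to the k best-scoring genes, columns ordered by rank
#' (best first).
#'
#' @param m A [labeled_expression_matrix()].
#' @param ranking A `fisher_ranking` from [fisher_scores()] on `m`.
#' @param k Number of genes to keep, `1 <= k <= p`.
#' @return A reduced [labeled_expression_matrix()].
#' @export
take_top <- function(m, ranking, k) {
  stopifnot(inherits(m, "lem"), inherits(ranking, "fisher_ranking"))
  p <- ncol(m$values)
  if (k < 1L || k > p) stop("k must be in 1..", p)
  lem_subset_genes(m, ranking$order[seq_len(k)])
}

#' Write a Fisher ranking as TSV
#'
#' Emits `rank<TAB>gene_id<TAB>fisher_score`.
#'
#' @param ranking A `fisher_ranking`.
#' @param path Output path.
#' @export
write_fisher_ranking <- function(ranking, path) {
  df <- data.frame(rank = seq_along(ranking$order),
                   gene_id = names(ranking$scores)[ranking$order],
                   fisher_score = unname(ranking$scores[ranking$order]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
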