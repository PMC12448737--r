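#' Discretize expression values for mutual-information estimation
#'
#' Per-gene equal-frequency (quantile) binning into at most `n_bins` codes.
#' Duplicated quantile edges (heavily tied genes) are collapsed, so the
#' realized bin count can be smaller; constant genes collapse to a single
#' code 0 and are flagged.
#'
#' @param m A [labeled_expression_matrix()].
#' @param n_bins Target number of bins (default 5, >= 2).
#' @return An object of class `discretized_matrix`: `codes` (integer matrix
#'   samples x genes, values `0..B-1`), `bin_edges` (per-gene interior
#'   edges), `n_bins`, `realized_bins`, `constant` (flags).
#' @export
discretize <- function(m, n_bins = 5L) {
  stopifnot(inherits(m, "lem"), n_bins >= 2L)
  p <- ncol(m$values)
  codes <- matrix(0L, nrow(m$values), p,
                  dimnames = dimnames(m$values))
  edges <- vector("list", p)
  realized <- integer(p)
  for (j in seq_len(p)) {
    x <- m$values[, j]
    qs <- stats::quantile(x, probs = seq_len(n_bins - 1L) / n_bins,
                          names = FALSE, type = 7)
    e <- unique(qs)
    e <- e[e > min(x) & e < max(x)]   # edges at the extremes bin nothing off
    if (length(e) == 0L && min(x) == max(x)) {
      edges[[j]] <- numeric(0)
      realized[j] <- 1L
      next
    }
    codes[, j] <- .bincode(x, c(-Inf, e, Inf), right = TRUE) - 1L
    edges[[j]] <- e
    realized[j] <- length(unique(codes[, j]))
  }
  constant <- realized == 1L
  if (any(constant)) {
    message(sprintf("%d constant gene(s) collapsed to a single bin",
                    sum(constant)))
  }
  structure(list(codes = codes, bin_edges = edges, n_bins = as.integer(n_bins),
                 realized_bins = realized, constant = constant,
                 labels = m$labels, gene_ids = m$gene_ids),
            class = "discretized_matrix")
}

#' Plug-in mutual information of two discrete code vectors
#'
#' \deqn{I(a,b) = \sum_{u,v} \hat p(u,v) \ln\frac{\hat p(u,v)}{\hat p(u)\hat p(v)}}
#' over the empirical joint distribution, in nats, with `0 ln 0 = 0`. Tiny
#' negative values from floating-point cancellation are clamped to 0.
#'
#' @param a,b Integer code vectors of equal length.
#' @return Non-negative mutual information in nats.
#' @export
mutual_information <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  n <- length(a)
  stopifnot(n >= 1L)
  joint <- table(a, b) / n
  pa <- rowSums(joint)
  pb <- colSums(joint)
  pr <- outer(pa, pb)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / pr[nz]))
  if (mi < -1e-12) stop("negative mutual information; numerical failure")
  max(mi, 0)
}

# fast path used by the greedy loop: codes are small non-negative integers
.mi_codes <- function(a, b, na, nb) {
  n <- length(a)
  cnt <- tabulate(a * nb + b + 1L, nbins = na * nb)
  joint <- cnt / n
  pj <- matrix(joint, nrow = nb)
  pa <- colSums(pj)
  pb <- rowSums(pj)
  pr <- as.vector(pb %o% pa)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / pr[nz]))
  max(mi, 0)
}

#' Greedy minimum-redundancy maximum-relevance ranking
#'
#' Reorders candidate genes by repeatedly selecting the feature f maximizing
#' relevance minus redundancy (the difference form, "MID"):
#'
#' \deqn{\max_{f \in \Phi_t} \left[ I(f, t) - \frac{1}{m}\sum_{f_i \in \Phi_s} I(f, f_i) \right]}
#'
#' where t is the class label (treated as an already-discrete 2-state
#' variable), \eqn{\Phi_s} the already selected set of size m, and I the
#' plug-in estimator of [mutual_information()] on discretized codes. The
#' first pick is pure relevance (redundancy defined as 0 on the empty set);
#' ties break by ascending original gene index.
#'
#' @param d A `discretized_matrix` from [discretize()].
#' @param labels Binary label vector (defaults to the labels carried by `d`).
#' @param n_select Number of genes to rank, `1 <= n_select <= p`.
#' @return An object of class `mrmr_ranking`: `order` (gene indices in
#'   selection order), `gene_ids`, and per-step `relevance`, `redundancy`,
#'   `objective` (nats).
#' @export
mrmr_rank <- function(d, labels = d$labels, n_select) {
  stopifnot(inherits(d, "discretized_matrix"))
  p <- ncol(d$codes)
  if (n_select < 1L || n_select > p) stop("n_select must be in 1..", p)
  y <- as.integer(labels)
  stopifnot(length(y) == nrow(d$codes))
  ny <- max(y) + 1L
  nb <- max(d$codes) + 1L
  relevance <- vapply(seq_len(p), function(j) {
    .mi_codes(d$codes[, j], y, nb, ny)
  }, numeric(1))
  selected <- integer(0)
  red_sum <- numeric(p)       # running sum of I(f, f_i) over selected f_i
  rec_rel <- rec_red <- rec_obj <- numeric(n_select)
  candidates <- rep(TRUE, p)
  for (step in seq_len(n_select)) {
    m_sel <- length(selected)
    red <- if (m_sel == 0L) numeric(p) else red_sum / m_sel
    obj <- relevance - red
    obj[!candidates] <- -Inf
    pick <- which.max(obj)    # which.max returns the first (lowest-index) max
    selected <- c(selected, pick)
    candidates[pick] <- FALSE
    rec_rel[step] <- relevance[pick]
    rec_red[step] <- if (m_sel == 0L) 0 else red[pick]
    rec_obj[step] <- if (m_sel == 0L) relevance[pick] else obj[pick]
    if (step < n_select) {
      newc <- d$codes[, pick]
      idx <- which(candidates)
      red_sum[idx] <- red_sum[idx] + vapply(idx, function(j) {
        .mi_codes(d$codes[, j], newc, nb, nb)
      }, numeric(1))
    }
  }
  structure(list(order = selected, gene_ids = d$gene_ids[selected],
                 relevance = rec_rel, redundancy = rec_red,
                 objective = rec_obj),
            class = "mrmr_ranking")
}

#' @export
print.mrmr_ranking <- function(x, ...) {
  cat(sprintf("mRMR ranking of %d genes; first pick: %s (relevance %.4g nats)\n",
              length(x$order), x$gene_ids[1L], x$relevance[1L]))
  invisible(x)
}

#' Write an mRMR ranking as TSV
#'
#' Emits `rank<TAB>gene_id<TAB>relevance_nats<TAB>redundancy_nats<TAB>objective`.
#'
#' @param ranking An `mrmr_ranking`.
#' @param path Output path.
#' @export
write_mrmr_ranking <- function(ranking, path) {
  df <- data.frame(rank = seq_along(ranking$order),
                   gene_id = ranking$gene_ids,
                   relevance_nats = ranking$relevance,
                   redundancy_nats = ranking$redundancy,
                   objective = ranking$objective)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
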