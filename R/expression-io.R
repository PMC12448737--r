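#' Labeled expression matrix
#'
#' The central data container of the package: a samples x genes matrix of
#' continuous (log2-scale) expression values together with per-sample binary
#' class labels (1 = case, 0 = control).
#'
#' @param values Numeric matrix, rows = samples, columns = genes. All values
#'   must be finite.
#' @param labels Integer/numeric vector of 0/1 class labels, one per row.
#' @param sample_ids Character vector of unique sample identifiers. Defaults
#'   to the rownames of `values`.
#' @param gene_ids Character vector of unique gene identifiers. Defaults to
#'   the colnames of `values`.
#'
#' @return An object of class `lem` (list with elements `values`,
#'   `sample_ids`, `gene_ids`, `labels`).
#' @export
labeled_expression_matrix <- function(values, labels,
                                      sample_ids = rownames(values),
                                      gene_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  labels <- as.integer(labels)
  if (nrow(values) != length(sample_ids) || nrow(values) != length(labels)) {
    stop("row count must equal |sample_ids| and |labels|")
  }
  if (ncol(values) != length(gene_ids)) {
    stop("column count must equal |gene_ids|")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicated gene id: ", gene_ids[duplicated(gene_ids)][1L])
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample id: ", sample_ids[duplicated(sample_ids)][1L])
  }
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (!all(is.finite(values))) stop("expression values must be finite")
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 gene_ids = gene_ids, labels = labels),
            class = "lem")
}

#' @export
print.lem <- function(x, ...) {
  cat(sprintf("labeled expression matrix: %d samples x %d genes (%d case / %d control)\n",
              nrow(x$values), ncol(x$values), sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' @export
dim.lem <- function(x) dim(x$values)

# column subset preserving labels; j = gene index or id vector
lem_subset_genes <- function(m, j) {
  labeled_expression_matrix(m$values[, j, drop = FALSE], m$labels,
                            sample_ids = m$sample_ids)
}

#' Read an expression matrix and its sample labels
#'
#' Reads a genes x samples TSV (first column = gene id, header row = sample
#' ids) plus a two-column `sample_id<TAB>label` TSV, and returns the matrix
#' transposed to samples x genes with sample order following the label file.
#' Genes containing any missing value are dropped with a message.
#'
#' @param expr_path Path to the expression TSV.
#' @param labels_path Path to the labels TSV (labels in \{0,1\}).
#' @return A [labeled_expression_matrix()].
#' @export
read_expression_matrix <- function(expr_path, labels_path) {
  expr <- utils::read.delim(expr_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  gene_ids <- as.character(expr[[1L]])
  if (anyDuplicated(gene_ids)) {
    stop("duplicated gene id: ", gene_ids[duplicated(gene_ids)][1L])
  }
  vals <- as.matrix(expr[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  lab <- utils::read.delim(labels_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  sample_ids <- as.character(lab[[1L]])
  labels <- lab[[2L]]
  missing_lab <- setdiff(colnames(vals), sample_ids)
  missing_expr <- setdiff(sample_ids, colnames(vals))
  if (length(missing_lab) || length(missing_expr)) {
    msg <- character(0)
    if (length(missing_lab)) {
      msg <- c(msg, paste0("samples missing labels: ",
                           paste(sort(missing_lab), collapse = ", ")))
    }
    if (length(missing_expr)) {
      msg <- c(msg, paste0("labeled samples missing expression: ",
                           paste(sort(missing_expr), collapse = ", ")))
    }
    stop(paste(msg, collapse = "; "))
  }
  vals <- vals[, sample_ids, drop = FALSE]
  keep <- !apply(vals, 1L, anyNA)
  if (any(!keep)) {
    message(sprintf("dropped %d gene(s) with missing values", sum(!keep)))
    vals <- vals[keep, , drop = FALSE]
    gene_ids <- gene_ids[keep]
  }
  labeled_expression_matrix(t(vals), labels, sample_ids = sample_ids,
                            gene_ids = gene_ids)
}

#' Write an expression matrix and labels in the package's TSV dialect
#'
#' Inverse of [read_expression_matrix()]: emits a genes x samples TSV and a
#' `sample_id<TAB>label` TSV.
#'
#' @param m A [labeled_expression_matrix()].
#' @param expr_path,labels_path Output paths.
#' @export
write_expression_matrix <- function(m, expr_path, labels_path) {
  df <- data.frame(gene_id = m$gene_ids, t(m$values), check.names = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = m$sample_ids, label = m$labels),
                     labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expr_path, labels_path))
}

#' Read a per-gene statistics table
#'
#' Ingests externally computed differential-expression statistics
#' (`gene_id<TAB>p_value<TAB>log_fc[<TAB>t_stat]`), e.g. moderated-t output
#' from GEO2R/limma, so that real-data users can apply the package's filters
#' to the exact statistics their study used.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with columns `gene_id`, `p_value`, `log_fc` and
#'   optionally `t_stat`.
#' @export
read_gene_stats <- function(path) {
  st <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(st)[1:3] <- c("gene_id", "p_value", "log_fc")
  validate_gene_stats(st)
}

validate_gene_stats <- function(st) {
  stopifnot(all(c("gene_id", "p_value", "log_fc") %in% names(st)))
  st$gene_id <- as.character(st$gene_id)
  if (anyDuplicated(st$gene_id)) {
    stop("duplicated gene id in stats table: ",
         st$gene_id[duplicated(st$gene_id)][1L])
  }
  if (any(st$p_value < 0 | st$p_value > 1, na.rm = TRUE)) {
    stop("p_value outside [0,1]")
  }
  if (!all(is.finite(st$log_fc))) stop("log_fc must be finite")
  st
}

#' Per-gene Welch two-sample t test
#'
#' Computes, for every gene, the Welch t statistic between case (label 1) and
#' control (label 0) samples, a two-sided p-value from the t distribution
#' with Welch-Satterthwaite degrees of freedom, and
#' `log_fc = mean(case) - mean(control)` (inputs are assumed log2-scale, so
#' the mean difference is a log2 fold-change). This is the package's built-in
#' stand-in for externally computed moderated-t tables, which can be ingested
#' verbatim through [read_gene_stats()] instead.
#'
#' Degenerate genes (zero variance in both classes) get `t = 0, p = 1` when
#' the class means agree and `p = 0` with `degenerate = TRUE` otherwise.
#'
#' @param m A [labeled_expression_matrix()]; both classes need >= 2 samples.
#' @return `data.frame` with columns `gene_id`, `p_value`, `log_fc`,
#'   `t_stat`, `degenerate`.
#' @export
per_gene_welch_t <- function(m) {
  stopifnot(inherits(m, "lem"))
  g1 <- m$labels == 1L
  g0 <- m$labels == 0L
  n1 <- sum(g1); n0 <- sum(g0)
  if (n1 < 2L || n0 < 2L) stop("each class needs at least 2 samples")
  x1 <- m$values[g1, , drop = FALSE]
  x0 <- m$values[g0, , drop = FALSE]
  m1 <- colMeans(x1); m0 <- colMeans(x0)
  v1 <- colSums(sweep(x1, 2L, m1)^2) / (n1 - 1)
  v0 <- colSums(sweep(x0, 2L, m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  diff <- m1 - m0
  tt <- diff / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  degen <- se2 == 0
  if (any(degen)) {
    same <- degen & diff == 0
    tt[same] <- 0; p[same] <- 1
    tt[degen & !same] <- sign(diff[degen & !same]) * Inf
    p[degen & !same] <- 0
  }
  data.frame(gene_id = m$gene_ids, p_value = unname(p),
             log_fc = unname(diff), t_stat = unname(tt),
             degenerate = unname(degen & diff != 0),
             stringsAsFactors = FALSE)
}

#' Filter genes by p-value
#'
#' Returns the gene ids with `p_value` strictly below `threshold`. The
#' permissive default of 0.25 retains a broad pool of candidate genes for
#' downstream supervised selection rather than enforcing a conventional
#' significance cutoff.
#'
#' @param stats A gene statistics `data.frame` (see [read_gene_stats()]).
#' @param threshold Probability in (0, 1]; strict `<` comparison.
#' @return Character vector of gene ids (possibly empty, with a warning).
#' @export
filter_by_pvalue <- function(stats, threshold = 0.25) {
  stats <- validate_gene_stats(stats)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 1)
  keep <- stats$gene_id[!is.na(stats$p_value) & stats$p_value < threshold]
  if (length(keep) == 0L) warning("no genes pass the p-value filter")
  keep
}

#' A study bundle: expression matrix plus per-gene statistics
#'
#' @param name Study name.
#' @param matrix A [labeled_expression_matrix()].
#' @param stats Optional gene-statistics table; computed with
#'   [per_gene_welch_t()] when omitted.
#' @return A list of class `dataset_bundle`.
#' @export
dataset_bundle <- function(name, matrix, stats = NULL) {
  stopifnot(inherits(matrix, "lem"))
  if (is.null(stats)) stats <- per_gene_welch_t(matrix)
  stats <- validate_gene_stats(stats)
  if (!all(stats$gene_id %in% matrix$gene_ids)) {
    stop("stats table contains gene ids absent from the matrix")
  }
  structure(list(name = as.character(name), matrix = matrix, stats = stats),
            class = "dataset_bundle")
}

#' Build the cross-study common-gene matrix
#'
#' Restricts each study to the intersection of the supplied per-study gene
#' sets and stacks all samples into one matrix S (samples x common genes,
#' gene columns in lexicographic order). No batch correction is applied; the
#' studies are concatenated as-is and a warning says so.
#'
#' @param bundles List of [dataset_bundle()] objects.
#' @param gene_sets List of character vectors, aligned 1:1 with `bundles`
#'   (typically per-study [filter_by_pvalue()] output).
#' @return A [labeled_expression_matrix()] over all samples.
#' @export
build_common_matrix <- function(bundles, gene_sets) {
  stopifnot(length(bundles) >= 1L, length(bundles) == length(gene_sets))
  common <- Reduce(intersect, lapply(gene_sets, as.character))
  common <- intersect(common,
                      Reduce(intersect, lapply(bundles, function(b) b$matrix$gene_ids)))
  if (length(common) == 0L) stop("empty gene intersection across studies")
  common <- sort(common)
  ids <- unlist(lapply(bundles, function(b) b$matrix$sample_ids))
  prefix <- anyDuplicated(ids) > 0L
  if (prefix) {
    message("duplicate sample ids across studies; prefixing with study name")
  }
  blocks <- lapply(bundles, function(b) b$matrix$values[, common, drop = FALSE])
  vals <- do.call(rbind, blocks)
  labels <- unlist(lapply(bundles, function(b) b$matrix$labels))
  sample_ids <- unlist(lapply(bundles, function(b) {
    if (prefix) paste(b$name, b$matrix$sample_ids, sep = ".") else b$matrix$sample_ids
  }))
  warning("studies concatenated without batch correction")
  labeled_expression_matrix(vals, labels, sample_ids = sample_ids,
                            gene_ids = common)
}

#' Select differentially expressed genes
#'
#' DEG call with the conventional thresholds: `p_value < p_max` and
#' `|log_fc| > min_abs_logfc`, both strict.
#'
#' @param stats Gene statistics table.
#' @param p_max P-value cutoff (default 0.05).
#' @param min_abs_logfc Absolute log2 fold-change cutoff (default 1).
#' @return Character vector of DEG ids.
#' @export
select_degs <- function(stats, p_max = 0.05, min_abs_logfc = 1.0) {
  stats <- validate_gene_stats(stats)
  stopifnot(p_max > 0, p_max < 1, min_abs_logfc >= 0)
  stats$gene_id[!is.na(stats$p_value) & stats$p_value < p_max &
                  abs(stats$log_fc) > min_abs_logfc]
}

#' Intersect per-study DEG sets with a selected gene subset
#'
#' Computes `(intersection of all DEG sets) intersect subset`, returned
#' sorted for deterministic downstream use.
#'
#' @param deg_sets List of character vectors (one DEG set per study).
#' @param subset Character vector (e.g. the final selected gene subset).
#' @return Sorted character vector; empty with a warning when disjoint.
#' @export
intersect_deg_with_subset <- function(deg_sets, subset) {
  common_degs <- Reduce(intersect, lapply(deg_sets, as.character))
  out <- sort(intersect(common_degs, as.character(subset)))
  if (length(out) == 0L) warning("no common genes between DEGs and subset")
  out
}
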