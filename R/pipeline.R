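#' Pipeline configuration
#'
#' One configuration object driving [run_attbiomarker()] end to end. Inputs
#' are either a list of studies (`bundles`) or a [synthetic_spec()]
#' (`synthetic`). Candidate subset sizes can be given explicitly (the grid
#' the study design calls for) or as `"auto"` to size Round 1 by
#' [detect_deflection()].
#'
#' @param bundles Optional list of [dataset_bundle()] objects.
#' @param synthetic Optional [synthetic_spec()] generating the studies.
#' @param prefilter_p Per-study p-value prefilter threshold (default 0.25).
#' @param fisher_sizes Integer vector of Round-1 candidate sizes, or
#'   `"auto"`.
#' @param mrmr_sizes Integer vector of Round-2 candidate sizes.
#' @param deg_p,deg_logfc DEG thresholds (defaults 0.05 and 1).
#' @param n_bins Discretization bins for mRMR (default 5).
#' @param variant AttCNN ablation variant name (default `"baseline"`).
#' @param train AttCNN [train_config()] template.
#' @param test_fraction,cv_folds Resampling controls (defaults 0.2 and 5).
#' @param seed Master seed; stage seeds are derived from it.
#' @param edge_list_path Optional interaction edge list for hub ranking.
#' @param output_dir Optional directory for artifact files.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(bundles = NULL, synthetic = NULL,
                            prefilter_p = 0.25,
                            fisher_sizes = "auto",
                            mrmr_sizes = c(2500L, 2000L, 1500L, 1000L),
                            deg_p = 0.05, deg_logfc = 1.0, n_bins = 5L,
                            variant = "baseline", train = train_config(),
                            test_fraction = 0.2, cv_folds = 5L, seed = 1L,
                            edge_list_path = NULL, output_dir = NULL) {
  if (is.null(bundles) && is.null(synthetic)) {
    stop("either bundles or a synthetic spec is required")
  }
  stopifnot(prefilter_p > 0, prefilter_p <= 1, deg_p > 0, deg_p < 1,
            deg_logfc >= 0)
  structure(list(bundles = bundles, synthetic = synthetic,
                 prefilter_p = prefilter_p, fisher_sizes = fisher_sizes,
                 mrmr_sizes = as.integer(mrmr_sizes), deg_p = deg_p,
                 deg_logfc = deg_logfc, n_bins = as.integer(n_bins),
                 variant = variant, train = train,
                 test_fraction = test_fraction,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 edge_list_path = edge_list_path, output_dir = output_dir),
            class = "pipeline_config")
}

# deterministic per-stage seed derivation: master seed xor a stage-name hash
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 1048573L
  bitwXor(as.integer(master), h) %% .Machine$integer.max
}

# evaluate one candidate gene matrix; skips the fold loop when the round
# has a single candidate (the winner is trivial) and only reports the
# retrain-on-train / held-out-test metrics
.evaluate_subset <- function(sub_m, cfg, plan, run_cv) {
  p2 <- plan
  if (!run_cv) p2$folds <- NULL
  cls <- switch(cfg$variant,
                baseline = attcnn_classifier(cfg = cfg$train),
                RFCL = attcnn_classifier(cfg = cfg$train, dense_units = 0L),
                RBAL = attcnn_classifier(cfg = cfg$train,
                                         attention_blocks = character(0)),
                WFAL = attcnn_classifier(cfg = cfg$train,
                                         attention_blocks = "after_conv2"),
                WSAL = attcnn_classifier(cfg = cfg$train,
                                         attention_blocks = "after_conv1"),
                stop("unknown model variant: ", cfg$variant))
  crossval_evaluate(cls, sub_m, p2)
}

#' Run the full biomarker-discovery pipeline
#'
#' Stages, in order: (1) per-study statistics (Welch t unless the bundle
#' carries an external table), the p < `prefilter_p` filter per study, and
#' the common-gene matrix S; (2) Fisher ranking on S, candidate subset
#' sizes (explicit grid or automatic deflection point), per-size evaluation
#' of the configured classifier, winner = highest held-out test accuracy
#' (ties: higher AUC, then smaller size); (3) mRMR reranking of the Round-1
#' winner, per-size evaluation, winner chosen the same way; (4) per-study
#' DEG sets intersected with the final subset; (5) optional degree-based hub
#' ranking of a supplied edge list. One stratified holdout, fixed at the
#' start, is reused for every round. All stage seeds derive from
#' `cfg$seed`.
#'
#' @param cfg A [pipeline_config()].
#' @return An object of class `pipeline_report` with per-stage artifacts:
#'   `filtered_sets`, `common_matrix`, `fisher` (ranking, sizes, reports,
#'   winner), `mrmr` (ditto), `final_genes`, `deg_sets`, `common_with_degs`,
#'   `hubs`, `seeds`, `config`.
#' @export
run_attbiomarker <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- function(name) message("[", name, "] ", appendLF = FALSE)

  stage("data")
  bundles <- cfg$bundles
  truth <- NULL
  if (is.null(bundles)) {
    syn <- cfg$synthetic
    syn$seed <- stage_seed(cfg$seed, "synthetic")
    gen <- generate_multistudy(syn)
    bundles <- gen$bundles
    truth <- gen$truth
  }
  message(length(bundles), " studies")

  stage("prefilter")
  filtered_sets <- lapply(bundles, function(b) {
    filter_by_pvalue(b$stats, cfg$prefilter_p)
  })
  names(filtered_sets) <- vapply(bundles, `[[`, character(1), "name")
  message(paste(vapply(filtered_sets, length, integer(1)), collapse = "/"),
          " genes pass p < ", cfg$prefilter_p)
  S <- suppressWarnings(build_common_matrix(bundles, filtered_sets))
  message("  common matrix: ", nrow(S$values), " samples x ",
          ncol(S$values), " genes")

  plan <- make_split_plan(S$labels, test_fraction = cfg$test_fraction,
                          k = cfg$cv_folds,
                          seed = stage_seed(cfg$seed, "split"))

  stage("fisher")
  ranking <- fisher_scores(S)
  sizes1 <- if (identical(cfg$fisher_sizes, "auto")) {
    sc <- ranking$scores[ranking$order]
    sc[is.infinite(sc)] <- max(sc[is.finite(sc)], 1)
    detect_deflection(sc)
  } else {
    sz <- cfg$fisher_sizes
    sz[sz <= ncol(S$values)]
  }
  if (length(sizes1) == 0L) stop("stage fisher: no usable candidate sizes")
  message("candidate sizes: ", paste(sizes1, collapse = ", "))
  run_cv1 <- length(sizes1) > 1L
  reports1 <- lapply(sizes1, function(k) {
    .evaluate_subset(take_top(S, ranking, k), cfg, plan, run_cv1)
  })
  names(reports1) <- as.character(sizes1)
  pick_winner <- function(sizes, reports) {
    acc <- vapply(reports, function(r) r$test$acc, numeric(1))
    auc <- vapply(reports, function(r) r$test$auc, numeric(1))
    order(-acc, -auc, sizes)[1L]
  }
  w1 <- pick_winner(sizes1, reports1)
  round1_matrix <- take_top(S, ranking, sizes1[w1])
  message("  round-1 winner: ", sizes1[w1], " genes (test acc ",
          sprintf("%.3f", reports1[[w1]]$test$acc), ")")

  stage("mrmr")
  sizes2 <- cfg$mrmr_sizes[cfg$mrmr_sizes <= ncol(round1_matrix$values)]
  if (length(sizes2) == 0L) stop("stage mrmr: no usable candidate sizes")
  disc <- discretize(round1_matrix, cfg$n_bins)
  mr <- mrmr_rank(disc, n_select = max(sizes2))
  run_cv2 <- length(sizes2) > 1L
  reports2 <- lapply(sizes2, function(k) {
    sub <- lem_subset_genes(round1_matrix, mr$order[seq_len(k)])
    .evaluate_subset(sub, cfg, plan, run_cv2)
  })
  names(reports2) <- as.character(sizes2)
  w2 <- pick_winner(sizes2, reports2)
  final_genes <- mr$gene_ids[seq_len(sizes2[w2])]
  message("  round-2 winner: ", sizes2[w2], " genes (test acc ",
          sprintf("%.3f", reports2[[w2]]$test$acc), ")")

  stage("degs")
  deg_sets <- lapply(bundles, function(b) {
    select_degs(b$stats, cfg$deg_p, cfg$deg_logfc)
  })
  names(deg_sets) <- names(filtered_sets)
  common_with_degs <- suppressWarnings(
    intersect_deg_with_subset(deg_sets, final_genes))
  message(length(common_with_degs), " genes common to DEGs and final subset")

  hubs <- NULL
  if (!is.null(cfg$edge_list_path)) {
    stage("hubs")
    hubs <- top_hubs_by_degree(read_edge_list(cfg$edge_list_path))
    message(nrow(hubs), " hubs ranked")
  }

  report <- structure(
    list(filtered_sets = filtered_sets, common_matrix = S,
         fisher = list(ranking = ranking, sizes = sizes1,
                       reports = reports1, winner_size = sizes1[w1]),
         mrmr = list(ranking = mr, sizes = sizes2, reports = reports2,
                     winner_size = sizes2[w2]),
         final_genes = final_genes, deg_sets = deg_sets,
         common_with_degs = common_with_degs, hubs = hubs, truth = truth,
         plan = plan,
         seeds = list(master = cfg$seed,
                      synthetic = stage_seed(cfg$seed, "synthetic"),
                      split = stage_seed(cfg$seed, "split")),
         config = cfg),
    class = "pipeline_report")
  if (!is.null(cfg$output_dir)) write_pipeline_report(report, cfg$output_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("biomarker pipeline report\n")
  cat(sprintf("  common matrix: %d samples x %d genes\n",
              nrow(x$common_matrix$values), ncol(x$common_matrix$values)))
  cat(sprintf("  round 1 winner: %d genes; round 2 winner: %d genes\n",
              x$fisher$winner_size, x$mrmr$winner_size))
  r2 <- x$mrmr$reports[[as.character(x$mrmr$winner_size)]]
  cat(sprintf("  final subset held-out: AUC %.4f  ACC %.4f\n",
              r2$test$auc, r2$test$acc))
  cat(sprintf("  genes common to DEGs and final subset: %d\n",
              length(x$common_with_degs)))
  invisible(x)
}

#' Write pipeline artifacts to disk
#'
#' Rankings as TSV, gene sets as one-id-per-line text, metrics and manifest
#' as JSON.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fisher_ranking(report$fisher$ranking,
                       file.path(dir, "fisher_ranking.tsv"))
  write_mrmr_ranking(report$mrmr$ranking, file.path(dir, "mrmr_ranking.tsv"))
  writeLines(report$final_genes, file.path(dir, "final_genes.txt"))
  writeLines(report$common_with_degs, file.path(dir, "common_with_degs.txt"))
  metrics <- list(
    fisher = lapply(report$fisher$reports, function(r) {
      list(test = as.list(r$test),
           cv_mean = if (!is.null(r$aggregate)) as.list(stats::setNames(
             r$aggregate$mean, r$aggregate$metric)) else NULL)
    }),
    mrmr = lapply(report$mrmr$reports, function(r) {
      list(test = as.list(r$test),
           cv_mean = if (!is.null(r$aggregate)) as.list(stats::setNames(
             r$aggregate$mean, r$aggregate$metric)) else NULL)
    }))
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(seeds = report$seeds,
                   fisher_winner = report$fisher$winner_size,
                   mrmr_winner = report$mrmr$winner_size,
                   n_final_genes = length(report$final_genes),
                   n_common_with_degs = length(report$common_with_degs),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$hubs)) {
    write_hub_ranking(report$hubs, file.path(dir, "hubs.tsv"))
  }
  invisible(dir)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; a
#' `synthetic:` block maps onto [synthetic_spec()] and a `train:` block
#' onto [train_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$synthetic)) {
    raw$synthetic <- do.call(synthetic_spec, raw$synthetic)
  }
  if (!is.null(raw$train)) raw$train <- do.call(train_config, raw$train)
  if (!is.null(raw$bundles)) {
    raw$bundles <- lapply(raw$bundles, function(b) {
      m <- read_expression_matrix(b$expr, b$labels)
      st <- if (!is.null(b$stats)) read_gene_stats(b$stats) else NULL
      dataset_bundle(b$name, m, st)
    })
  }
  do.call(pipeline_config, raw)
}
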