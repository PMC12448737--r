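#' Specification of a synthetic multi-study expression experiment
#'
#' Defines the generative model used to validate every pipeline stage
#' against known ground truth. Expression is Gaussian on the log2 scale:
#' null genes are `Normal(study baseline, noise_sd^2)`; each of
#' `n_informative` planted genes adds `effect_size * noise_sd` to the case
#' (label 1) mean; each redundant block re-emits one latent
#' class-informative signal `block_size` times with pairwise correlation
#' `rho` (exercising the redundancy term of mRMR); per-study per-gene
#' baseline offsets with sd `study_shift_sd` emulate uncorrected batch
#' structure between studies.
#'
#' Defaults mirror a three-study microarray case/control design of about
#' 150 samples with a few thousand genes.
#'
#' @param n_per_class Samples per class per study (default 25).
#' @param n_genes Total genes p (default 2000).
#' @param n_informative Planted singleton differential genes (default 50).
#' @param effect_size Mean shift delta in units of `noise_sd` (default 1.5).
#' @param n_redundant_blocks,block_size Redundant near-duplicate gene groups
#'   (default 10 blocks of 5).
#' @param rho Pairwise correlation within a block, in `[0, 1)`
#'   (default 0.95).
#' @param noise_sd Within-class standard deviation (default 1).
#' @param n_studies Number of studies (default 3).
#' @param study_shift_sd Sd of per-study per-gene baseline offsets
#'   (default 0.5).
#' @param seed Master seed (default 1).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = 25L, n_genes = 2000L,
                           n_informative = 50L, effect_size = 1.5,
                           n_redundant_blocks = 10L, block_size = 5L,
                           rho = 0.95, noise_sd = 1.0, n_studies = 3L,
                           study_shift_sd = 0.5, seed = 1L) {
  stopifnot(n_per_class >= 2L, n_genes >= 1L, n_informative >= 0L,
            effect_size >= 0, n_redundant_blocks >= 0L, block_size >= 1L,
            rho >= 0, rho < 1, noise_sd > 0, n_studies >= 1L,
            study_shift_sd >= 0)
  if (n_informative + n_redundant_blocks * block_size > n_genes) {
    stop("n_informative + n_redundant_blocks * block_size exceeds n_genes")
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 n_genes = as.integer(n_genes),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 n_redundant_blocks = as.integer(n_redundant_blocks),
                 block_size = as.integer(block_size), rho = rho,
                 noise_sd = noise_sd, n_studies = as.integer(n_studies),
                 study_shift_sd = study_shift_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# fixed gene-role layout shared by all studies: first n_informative ids are
# planted singletons, then the redundant blocks, then nulls; identities are
# deterministic so that studies agree by construction
.synthetic_layout <- function(spec) {
  ids <- sprintf("g%05d", seq_len(spec$n_genes))
  inf <- seq_len(spec$n_informative)
  blocks <- list()
  nxt <- spec$n_informative
  for (b in seq_len(spec$n_redundant_blocks)) {
    blocks[[sprintf("block%02d", b)]] <- ids[nxt + seq_len(spec$block_size)]
    nxt <- nxt + spec$block_size
  }
  list(gene_ids = ids, informative_ids = ids[inf], blocks = blocks)
}

#' Generate one synthetic study
#'
#' Draws one study's expression matrix and labels under the model of
#' [synthetic_spec()], computes its Welch-t statistics table, and returns
#' the bundle together with the ground truth. All draws derive from
#' `bitwXor(spec$seed, study_index)` so studies are independent yet
#' reproducible.
#'
#' @param spec A `synthetic_spec`.
#' @param study_index 1-based study number.
#' @return List with elements `bundle` (a [dataset_bundle()]) and `truth`
#'   (list: `informative_ids`, `blocks`, `mean_shift` per gene).
#' @export
generate_study <- function(spec, study_index = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"), study_index >= 1L)
  lay <- .synthetic_layout(spec)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(bitwXor(spec$seed, as.integer(study_index)))
  n <- 2L * spec$n_per_class
  p <- spec$n_genes
  y <- rep(c(0L, 1L), each = spec$n_per_class)
  baseline <- stats::rnorm(p, 0, spec$study_shift_sd)
  vals <- matrix(stats::rnorm(n * p, 0, spec$noise_sd), n, p)
  delta <- spec$effect_size * spec$noise_sd
  shift <- numeric(p)
  names(shift) <- lay$gene_ids
  shift[lay$informative_ids] <- delta
  a <- sqrt(spec$rho)
  for (bl in lay$blocks) {
    z <- stats::rnorm(n, 0, spec$noise_sd)     # shared latent noise
    j <- match(bl, lay$gene_ids)
    for (jj in j) {
      vals[, jj] <- a * z + sqrt(1 - spec$rho) * vals[, jj]
    }
    shift[bl] <- delta
  }
  vals <- vals + outer(y, shift) + matrix(baseline, n, p, byrow = TRUE)
  m <- labeled_expression_matrix(
    vals, y,
    sample_ids = sprintf("st%d_s%03d", study_index, seq_len(n)),
    gene_ids = lay$gene_ids)
  bundle <- dataset_bundle(sprintf("study%d", study_index), m)
  list(bundle = bundle,
       truth = list(informative_ids = lay$informative_ids,
                    blocks = lay$blocks, mean_shift = shift))
}

#' Generate a multi-study synthetic experiment
#'
#' Studies share the gene universe and the identities of the planted genes
#' but have independent baselines and noise.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `bundles` (list of [dataset_bundle()]) and `truth`.
#' @export
generate_multistudy <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  studies <- lapply(seq_len(spec$n_studies), function(i) generate_study(spec, i))
  list(bundles = lapply(studies, `[[`, "bundle"),
       truth = studies[[1L]]$truth)
}

#' Write a synthetic study to the package's TSV dialect
#'
#' Emits the expression, labels and stats TSVs that [read_expression_matrix()]
#' and [read_gene_stats()] ingest, plus the ground truth as JSON.
#'
#' @param study Output of [generate_study()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix (default the bundle name).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_study <- function(study, dir, prefix = study$bundle$name) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ep <- file.path(dir, paste0(prefix, "_expr.tsv"))
  lp <- file.path(dir, paste0(prefix, "_labels.tsv"))
  sp <- file.path(dir, paste0(prefix, "_stats.tsv"))
  tp <- file.path(dir, paste0(prefix, "_truth.json"))
  write_expression_matrix(study$bundle$matrix, ep, lp)
  utils::write.table(study$bundle$stats[, c("gene_id", "p_value", "log_fc", "t_stat")],
                     sp, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(study$truth, tp, auto_unbox = TRUE, digits = NA)
  invisible(c(ep, lp, sp, tp))
}
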