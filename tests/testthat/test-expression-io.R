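write_fixture <- function(expr_df, labels_df) {
  ep <- tempfile(fileext = ".tsv"); lp <- tempfile(fileext = ".tsv")
  write.table(expr_df, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(labels_df, lp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(expr = ep, labels = lp)
}

test_that("reading transposes to samples x genes and follows the label file order", {
  expr <- data.frame(gene_id = c("g1", "g2", "g3"),
                     s1 = c(1, 2, 3), s2 = c(4, 5, 6),
                     s3 = c(7, 8, 9), s4 = c(10, 11, 12))
  labels <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                       label = c(0, 0, 1, 1))
  fx <- write_fixture(expr, labels)
  m <- read_expression_matrix(fx$expr, fx$labels)
  expect_equal(dim(m$values), c(4L, 3L))
  expect_equal(m$labels, c(0L, 0L, 1L, 1L))
  expect_equal(m$values["s2", "g3"], 6)
  # label file order wins, not expression column order
  labels_rev <- labels[4:1, ]
  fx2 <- write_fixture(expr, labels_rev)
  m2 <- read_expression_matrix(fx2$expr, fx2$labels)
  expect_equal(m2$sample_ids, c("s4", "s3", "s2", "s1"))
  expect_equal(m2$values["s4", "g1"], 10)
})

test_that("genes with missing values are dropped with a message", {
  expr <- data.frame(gene_id = c("g1", "g2", "g3"),
                     s1 = c(1, NA, 3), s2 = c(4, 5, 6),
                     s3 = c(7, 8, 9), s4 = c(10, 11, 12))
  labels <- data.frame(sample_id = paste0("s", 1:4), label = c(0, 0, 1, 1))
  fx <- write_fixture(expr, labels)
  expect_message(m <- read_expression_matrix(fx$expr, fx$labels),
                 "dropped 1 gene")
  expect_equal(m$gene_ids, c("g1", "g3"))
  expect_equal(dim(m$values), c(4L, 2L))
})

test_that("id mismatches and duplicates are hard errors", {
  expr <- data.frame(gene_id = c("g1", "g2"),
                     s1 = c(1, 2), s2 = c(3, 4), s3 = c(5, 6), s4 = c(7, 8))
  labels3 <- data.frame(sample_id = c("s1", "s2", "s3"), label = c(0, 1, 1))
  fx <- write_fixture(expr, labels3)
  expect_error(read_expression_matrix(fx$expr, fx$labels),
               "samples missing labels: s4")
  expr_dup <- data.frame(gene_id = c("g1", "g1"), s1 = c(1, 2), s2 = c(3, 4))
  labels2 <- data.frame(sample_id = c("s1", "s2"), label = c(0, 1))
  fx2 <- write_fixture(expr_dup, labels2)
  expect_error(read_expression_matrix(fx2$expr, fx2$labels),
               "duplicated gene id: g1")
})

test_that("welch statistics agree with stats::t.test and handle degenerate genes", {
  set.seed(101)
  y <- rep(c(0L, 1L), c(9, 11))
  X <- matrix(rnorm(20 * 6), 20, 6)
  X[, 1] <- 0                               # flat gene
  X[, 2] <- ifelse(y == 1, 2, 0)            # zero variance, shifted
  m <- tiny_lem(X, y)
  st <- per_gene_welch_t(m)
  expect_equal(st$t_stat[1], 0)
  expect_equal(st$p_value[1], 1)
  expect_equal(st$log_fc[1], 0)
  expect_true(st$degenerate[2])
  expect_equal(st$p_value[2], 0)
  expect_equal(st$log_fc[2], 2)
  for (j in 3:6) {
    tt <- t.test(X[y == 1, j], X[y == 0, j])
    expect_equal(st$t_stat[j], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(st$p_value[j], tt$p.value, tolerance = 1e-10)
    expect_equal(st$log_fc[j], unname(diff(rev(tt$estimate))), tolerance = 1e-10)
  }
  expect_error(per_gene_welch_t(tiny_lem(X[c(1, 20, 19), ], y[c(1, 20, 19)])),
               "at least 2 samples")
})

test_that("welch p-values are approximately uniform under the null", {
  set.seed(202)
  y <- rep(c(0L, 1L), each = 25)
  X <- matrix(rnorm(50 * 1000), 50, 1000)
  st <- per_gene_welch_t(tiny_lem(X, y))
  frac05 <- mean(st$p_value < 0.05)
  expect_gte(frac05, 0.03)
  expect_lte(frac05, 0.07)
})

test_that("p-value filter is strict and monotone in the threshold", {
  st <- data.frame(gene_id = c("g1", "g2", "g3"),
                   p_value = c(0.1, 0.25, 0.3), log_fc = c(0, 0, 0))
  expect_equal(filter_by_pvalue(st, 0.25), "g1")
  expect_setequal(filter_by_pvalue(st, 1.0), c("g1", "g2", "g3"))
  expect_warning(out <- filter_by_pvalue(st, 0.05), "no genes pass")
  expect_length(out, 0)
  set.seed(7)
  st2 <- data.frame(gene_id = sprintf("g%03d", 1:200),
                    p_value = runif(200), log_fc = rnorm(200))
  thresholds <- sort(runif(6))
  for (i in seq_len(length(thresholds) - 1)) {
    expect_true(all(filter_by_pvalue(st2, thresholds[i]) %in%
                      filter_by_pvalue(st2, thresholds[i + 1])))
  }
})

test_that("common-matrix gene universe equals a nested-loop intersection oracle", {
  set.seed(33)
  make_bundle <- function(name, genes, n = 6) {
    vals <- matrix(rnorm(n * length(genes)), n, length(genes),
                   dimnames = list(sprintf("%s_s%d", name, 1:n), genes))
    dataset_bundle(name, labeled_expression_matrix(
      vals, rep(c(0L, 1L), length.out = n)))
  }
  for (rep_i in 1:5) {
    universe <- sprintf("g%02d", 1:30)
    sets <- lapply(1:3, function(i) sample(universe, sample(10:25, 1)))
    bundles <- lapply(1:3, function(i) make_bundle(paste0("b", i), universe))
    # naive oracle: keep g iff present in every set
    oracle <- sort(Filter(function(g) all(vapply(sets, function(s) g %in% s,
                                                 logical(1))), universe))
    S <- suppressWarnings(build_common_matrix(bundles, sets))
    expect_equal(S$gene_ids, oracle)
    expect_equal(nrow(S$values), 18L)
  }
  b <- make_bundle("solo", sprintf("g%02d", 1:8))
  S1 <- suppressWarnings(build_common_matrix(list(b), list(c("g03", "g01"))))
  expect_equal(S1$gene_ids, c("g01", "g03"))
  expect_error(suppressWarnings(
    build_common_matrix(lapply(1:2, function(i) make_bundle(paste0("x", i),
                                                            c("a", "b"))),
                        list("a", "b"))),
    "empty gene intersection")
})

test_that("DEG selection applies both strict thresholds", {
  st <- data.frame(gene_id = paste0("g", 1:4),
                   p_value = c(0.01, 0.01, 0.2, 0.04),
                   log_fc = c(1.5, 0.5, 2.0, -1.2))
  expect_setequal(select_degs(st), c("g1", "g4"))
  expect_setequal(select_degs(st, p_max = 0.999, min_abs_logfc = 0),
                  paste0("g", 1:4))
})

test_that("DEG/subset intersection is sorted and warns when empty", {
  expect_equal(intersect_deg_with_subset(list(c("a", "b"), c("b", "c")),
                                         c("z", "b")), "b")
  expect_warning(out <- intersect_deg_with_subset(list(c("a", "b")), "q"),
                 "no common genes")
  expect_length(out, 0)
  expect_equal(intersect_deg_with_subset(list(c("d", "c", "b")), c("c", "b", "d")),
               c("b", "c", "d"))
})
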