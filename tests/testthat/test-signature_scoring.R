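test_that("center_genes zeroes every row mean across all samples", {
  m <- rbind(g1 = c(2, 4, 6), g2 = c(5, 5, 5), g3 = c(-1, 0, 1))
  colnames(m) <- paste0("s", 1:3)
  got <- center_genes(m)$values
  expect_equal(unname(got["g1", ]), c(-2, 0, 2))
  expect_equal(unname(got["g2", ]), c(0, 0, 0))
  expect_equal(unname(got["g3", ]), c(-1, 0, 1))  # already centered: unchanged
  expect_true(all(abs(rowMeans(got)) < 1e-12))
})

test_that("score_gene_set averages set genes then replicates, dropping absentees", {
  m <- rbind(g1 = c(-2, 0, 2), g2 = c(0, 0, 0))
  colnames(m) <- paste0("s", 1:3)
  singletons <- sample_grouping(c(s1 = "A", s2 = "B", s3 = "C"))
  sc <- score_gene_set(m, c("g1", "g2"), singletons)
  expect_equal(as.numeric(sc), c(-1, 0, 1))

  expect_warning(sc <- score_gene_set(m, c("g1", "gX"), singletons), "absent")
  expect_equal(as.numeric(sc), c(-2, 0, 2))

  one_group <- sample_grouping(c(s1 = "A", s2 = "A", s3 = "A"))
  expect_equal(as.numeric(score_gene_set(m, "g1", one_group)), 0)

  expect_error(score_gene_set(m, "gX", singletons, set_name = "S"), "'S'")
  expect_error(score_gene_set(m, "g1", sample_grouping(c(s1 = "A"))),
               "without a group")
})

test_that("rank table: sort order, planted ordering and tie determinism", {
  # scores (0.5, -1.2, 3.0) -> ranks (2, 3, 1)
  m <- rbind(g1 = c(0.5, -1.2, 3.0) - mean(c(0.5, -1.2, 3.0)))
  colnames(m) <- paste0("s", 1:3)
  gr <- sample_grouping(c(s1 = "A", s2 = "B", s3 = "C"))
  rt <- build_rank_table(m, list(S = "g1"), gr)
  expect_identical(unname(rt$ranks[, "S"]), c(2L, 3L, 1L))

  # noise-free planted ordering is recovered exactly through the full path
  spec <- synthetic_spec(seed = 3, n_genes = 100, n_groups = 5, replicates = 2,
                         signatures = list(S1 = list(size = 20, delta = 2)),
                         noise_sd = 1e-9)
  comp <- generate_expression_compendium(spec)
  coll <- suppressMessages(collapse_probes_max_sd(comp$expr, comp$probe_map))
  rt <- build_rank_table(center_genes(coll), comp$sets["S1"], comp$grouping)
  expect_identical(comp$truth$ordering$S1,
                   rownames(rt$ranks)[order(rt$ranks[, "S1"])])

  # exact score ties break by group order -> each column a permutation
  tied <- rbind(g1 = c(1, 1, 1) - 1)
  colnames(tied) <- paste0("s", 1:3)
  rt <- build_rank_table(tied, list(S = "g1"), gr)
  expect_identical(unname(rt$ranks[, "S"]), c(1L, 2L, 3L))
})

test_that("rank table equals the brute-force oracle on random compendia", {
  set.seed(11)
  for (i in 1:25) {
    m <- random_expr(200, 12)
    gr <- round_robin_grouping(colnames(m), 4)
    sets <- lapply(1:5, function(j) sample(rownames(m), sample(10:30, 1)))
    names(sets) <- paste0("S", 1:5)
    got <- build_rank_table(center_genes(m), sets, gr)
    want <- oracle_rank_table(m, sets, gr)
    expect_equal(got$scores, want$scores, tolerance = 1e-12)
    expect_identical(got$ranks, matrix(as.integer(want$ranks),
                                       nrow = nrow(want$ranks),
                                       dimnames = dimnames(want$ranks)))
  }
})

test_that("scores are invariant to adding a constant to the raw matrix", {
  set.seed(4)
  m <- random_expr(80, 9)
  gr <- round_robin_grouping(colnames(m), 3)
  sets <- list(S1 = sample(rownames(m), 15), S2 = sample(rownames(m), 8))
  a <- build_rank_table(center_genes(m), sets, gr)
  b <- build_rank_table(center_genes(m + 3.7), sets, gr)
  expect_equal(a$scores, b$scores, tolerance = 1e-12)
})

test_that("fold-change family signature applies prefix and log2 threshold", {
  m <- rbind(SLC7A5 = c(4, 4, 1.5, 1.5), SLC2A1 = c(1.8, 1.8, 1, 1),
             KRT20  = c(4, 4, 1, 1))
  colnames(m) <- paste0("s", 1:4)
  gr <- sample_grouping(c(s1 = "SI", s2 = "SI", s3 = "pool", s4 = "pool"))
  got <- derive_fold_change_signature(m, gr, "SI", "pool", "SLC", min_fold = 2)
  expect_identical(got, "SLC7A5")  # diff 2.5 >= 1; SLC2A1 diff 0.8 out; KRT20 prefix out
  expect_warning(empty <- derive_fold_change_signature(m, gr, "SI", "pool", "ABC"),
                 "prefix")
  expect_identical(empty, character(0))
  expect_error(derive_fold_change_signature(m, gr, "nope", "pool", "SLC"),
               "nope")
})

test_that("pca_project: rank constraint, duplication invariance, sign fix", {
  m <- random_expr(20, 2)
  p <- pca_project(m)
  expect_identical(ncol(p$scores), 1L)
  expect_equal(p$var_explained, 1.0)

  set.seed(9)
  m <- random_expr(30, 4)
  dup <- cbind(m, m)
  colnames(dup) <- paste0("s", 1:8)
  p <- pca_project(expression_matrix(dup, "gene"))
  expect_equal(unname(p$scores[1:4, ]), unname(p$scores[5:8, ]),
               tolerance = 1e-8)

  p <- pca_project(m)
  for (j in seq_len(ncol(p$loadings)))
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1 + 1e-12)

  expect_error(pca_project(m, feature_filter = "nothere"), "eliminates")
})

test_that("pca_project agrees with a direct eigendecomposition oracle", {
  set.seed(21)
  for (i in 1:10) {
    m <- random_expr(20, 6)
    p <- pca_project(m)
    x <- scale(t(m), center = TRUE, scale = FALSE)
    eig <- eigen(crossprod(x) / (nrow(x) - 1), symmetric = TRUE)
    keep <- seq_len(ncol(p$scores))
    expect_equal(p$var_explained, (eig$values / sum(eig$values))[keep],
                 tolerance = 1e-8)
    for (j in keep)  # coordinates agree up to the documented sign convention
      expect_equal(abs(unname(p$scores[, j])), abs(unname(x %*% eig$vectors[, j]))[, 1],
                   tolerance = 1e-8)
  }
})

test_that("pca separates planted clusters along PC1", {
  spec <- synthetic_spec(seed = 13, n_genes = 200, n_groups = 2, replicates = 5,
                         signatures = list(S = list(size = 80, shifts = c(3, -3))),
                         noise_sd = 0.3)
  comp <- generate_expression_compendium(spec)
  p <- pca_project(comp$gene_level)
  grp <- unclass(comp$grouping)[rownames(p$scores)]
  margin <- min(p$scores[grp == "G01", 1]) - max(p$scores[grp == "G02", 1])
  expect_true(abs(margin) > 0 &&
                (all(p$scores[grp == "G01", 1] > p$scores[grp == "G02", 1]) ||
                 all(p$scores[grp == "G01", 1] < p$scores[grp == "G02", 1])))
})

test_that("rank tables serialize in the published layout", {
  m <- random_expr(30, 6)
  gr <- round_robin_grouping(colnames(m), 3)
  rt <- build_rank_table(center_genes(m), list(A = rownames(m)[1:5],
                                               B = rownames(m)[6:10]), gr)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rank_table(rt, path)
  got <- read.delim(path, check.names = FALSE)
  expect_identical(names(got), c("group", "A", "B"))
  expect_identical(got$group, rt$groups)
  expect_true(all(vapply(got[-1], function(col) all(sort(col) == 1:3), TRUE)))
})
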