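test_that("spec validation rejects impossible worlds", {
  expect_error(synthetic_spec(signatures = list(S = list(size = 2000, delta = 1))),
               "exceed")
  expect_error(synthetic_spec(censoring_rate = 1), "censoring_rate")
  expect_error(synthetic_spec(noise_sd = 0), "noise_sd")
  expect_error(synthetic_spec(n_coupled = 5000), "n_coupled")
})

test_that("compendium generation is a pure function of (spec, seed)", {
  spec <- synthetic_spec(seed = 101, n_genes = 120, n_groups = 4,
                         signatures = list(S = list(size = 15, delta = 1)))
  a <- generate_expression_compendium(spec)
  b <- generate_expression_compendium(spec)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$probe_map, b$probe_map)
  expect_identical(a$truth, b$truth)
  c <- generate_expression_compendium(synthetic_spec(seed = 102, n_genes = 120,
        n_groups = 4, signatures = list(S = list(size = 15, delta = 1))))
  expect_false(identical(a$expr$values, c$expr$values))
})

test_that("noise-free limit recovers the planted order exactly", {
  spec <- synthetic_spec(seed = 31, n_genes = 150, n_groups = 5,
                         signatures = list(S = list(size = 30, delta = 1)),
                         noise_sd = 1e-10, probe_offset_sd = 1e-10)
  comp <- generate_expression_compendium(spec)
  coll <- suppressMessages(collapse_probes_max_sd(comp$expr, comp$probe_map))
  rt <- build_rank_table(center_genes(coll), comp$sets["S"], comp$grouping)
  expect_identical(rownames(rt$ranks)[order(rt$ranks[, "S"])],
                   comp$truth$ordering$S)
})

test_that("probe expansion is consistent with the map and exercises collapse", {
  spec <- synthetic_spec(seed = 5, n_genes = 100, n_groups = 3,
                         signatures = list(S = list(size = 10, delta = 1)))
  comp <- generate_expression_compendium(spec)
  expect_identical(comp$expr$level, "probe")
  expect_setequal(unique(unname(comp$probe_map)), rownames(comp$gene_level$values))
  np <- table(unname(comp$probe_map))
  expect_true(all(np >= 2 & np <= 4))
  coll <- suppressMessages(collapse_probes_max_sd(comp$expr, comp$probe_map))
  # the informative probe (suffix _p1) carries the gene profile verbatim
  chosen <- attr(coll, "probe_chosen")
  frac_informative <- mean(endsWith(unname(chosen), "_p1"))
  expect_gt(frac_informative, 0.9)
})

test_that("emitted fixtures round-trip through the readers without loss", {
  spec <- synthetic_spec(seed = 77, n_genes = 80, n_groups = 6, replicates = 2,
                         signatures = list(S = list(size = 10, delta = 1)),
                         n_drugs = 5, n_lines = 12, n_coupled = 6)
  dir <- withr::local_tempdir()
  paths <- suppressMessages(write_synthetic_fixtures(spec, dir))
  comp <- generate_expression_compendium(spec)
  expr <- suppressMessages(read_expression_matrix(paths[["expr"]], level = "probe"))
  expect_identical(expr$values, comp$expr$values)
  expect_identical(unclass(read_sample_grouping(paths[["groups"]])),
                   unclass(comp$grouping))
  expect_identical(read_probe_map(paths[["probe_map"]]), comp$probe_map)
  got_sets <- read_gmt(paths[["gmt"]])
  expect_identical(got_sets$S, comp$sets$S)
  truth <- jsonlite::fromJSON(paths[["truth"]])
  expect_identical(truth$ordering$S, comp$truth$ordering$S)
})

test_that("gi50 generator plants recoverable coupling and errors on bad input", {
  spec <- synthetic_spec(seed = 9, n_genes = 200, n_groups = 30, replicates = 1,
                         n_coupled = 10, n_drugs = 8,
                         signatures = list(S = list(size = 5, delta = 0)))
  comp <- generate_expression_compendium(spec)
  gi <- generate_gi50_matrix(spec, comp$gene_level)
  expect_identical(dim(gi$response), c(8L, 30L))
  expect_length(intersect(gi$truth$positive, gi$truth$negative), 0)
  # positive genes correlate positively with every drug, negative negatively
  cmat <- gene_drug_correlations(gi$expr, gi$response)
  expect_gt(min(rowMeans(cmat[gi$truth$positive, ])), 0)
  expect_lt(max(rowMeans(cmat[gi$truth$negative, ])), 0)

  one_line <- expression_matrix(
    matrix(1:5, 5, 1, dimnames = list(paste0("g", 1:5), "L1")), "gene")
  expect_error(generate_gi50_matrix(spec, one_line), ">= 2 cell lines")
})

test_that("survival generator: censoring-off limit and stochastic ordering", {
  spec0 <- synthetic_spec(seed = 41, censoring_rate = 0)
  coh <- generate_survival_cohort(spec0, rnorm(100))
  expect_true(all(coh$event == 1L))

  spec <- synthetic_spec(seed = 42, log_hr = log(2.5), censoring_rate = 0.2)
  scores <- rep(c(0, 1), each = 1000)
  coh <- generate_survival_cohort(spec, scores)
  coh$group <- factor(ifelse(coh$score > 0, "high", "low"),
                      levels = c("low", "high"))
  km_hi <- kaplan_meier(coh, "high")
  km_lo <- kaplan_meier(coh, "low")
  # at the shared grid of the low group's event times, high-score survival
  # must lie below (step functions evaluated by right-continuous lookup)
  s_at <- function(km, t) {
    i <- findInterval(t, km$time)
    ifelse(i == 0, 1, km$survival[pmax(i, 1)])
  }
  grid <- quantile(coh$time, c(0.2, 0.4, 0.6, 0.8))
  expect_true(all(s_at(km_hi, grid) < s_at(km_lo, grid)))
})

test_that("delta = 0 gives symmetric rank-1 frequencies", {
  n_groups <- 5
  wins <- integer(n_groups)
  for (i in 1:200) {
    spec <- synthetic_spec(seed = 1000 + i, n_genes = 60, n_groups = n_groups,
                           replicates = 2,
                           signatures = list(S = list(size = 20, delta = 0)))
    comp <- generate_expression_compendium(spec)
    rt <- build_rank_table(center_genes(comp$gene_level), comp$sets["S"],
                           comp$grouping)
    wins[which(rt$ranks[, "S"] == 1L)] <- wins[which(rt$ranks[, "S"] == 1L)] + 1L
  }
  gof <- sum((wins - 200 / n_groups)^2 / (200 / n_groups))
  expect_lt(gof, qchisq(0.999, df = n_groups - 1))
})
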