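#' Specification of a synthetic data world
#'
#' Bundles all parameters of the three generators. Defaults mirror the
#' experimental design the pipeline was built around: 3 replicates per group,
#' Gaussian log2 replicate noise of SD 0.5 (typical of RMA-summarized
#' arrays), one 50-gene planted signature with per-group mean shifts spaced
#' 1 log2 unit (= 2 noise SDs), 2-4 probe sets per gene of which one carries
#' the full signal, and an NCI60-shaped drug block (50 drugs x 59 lines,
#' 30 + 30 response-coupled genes).
#'
#' @param seed integer master seed; each generator derives its own stream
#'   from it (offsets +0 expression, +1 GI50, +2 survival)
#' @param n_genes,n_groups,replicates compendium dimensions
#' @param signatures named list; each element is `list(size =, delta =)` for
#'   equally spaced descending per-group shifts (group 1 strongest), or
#'   `list(size =, shifts = <numeric of length n_groups>)`
#' @param noise_sd replicate-level Gaussian noise SD (log2 units), > 0
#' @param baseline_mean,baseline_sd per-gene baseline log2 level
#' @param probes_min,probes_max probe sets per gene (uniform draw)
#' @param attenuation signal fraction carried by non-informative probes
#' @param probe_offset_sd per-probe additive jitter SD
#' @param n_decoy_sets,decoy_size random decoy gene sets added to the
#'   emitted collection
#' @param n_drugs,n_lines,n_coupled,coupling_sd,slope,response_sd GI50 block:
#'   number of drugs and cell lines, number of response-coupled genes (split
#'   half positive / half negative), SD of the per-line latent sensitivity
#'   factor, response slope and response noise SD
#' @param baseline_hazard,log_hr,censoring_rate survival block: exponential
#'   baseline hazard, log hazard ratio per unit signature score, approximate
#'   marginal censoring fraction in `[0, 1)`
#' @return validated list of class `SyntheticSpec`
#' @export
synthetic_spec <- function(seed = 1L,
                           n_genes = 1000L, n_groups = 10L, replicates = 3L,
                           signatures = list(S1 = list(size = 50L, delta = 1)),
                           noise_sd = 0.5,
                           baseline_mean = 7, baseline_sd = 1,
                           probes_min = 2L, probes_max = 4L,
                           attenuation = 0.2, probe_offset_sd = 0.25,
                           n_decoy_sets = 0L, decoy_size = 50L,
                           n_drugs = 50L, n_lines = 59L, n_coupled = 60L,
                           coupling_sd = 1, slope = 1, response_sd = 0.3,
                           baseline_hazard = 0.05, log_hr = log(2),
                           censoring_rate = 0.3) {
  spec <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
               n_groups = as.integer(n_groups),
               replicates = as.integer(replicates), signatures = signatures,
               noise_sd = noise_sd, baseline_mean = baseline_mean,
               baseline_sd = baseline_sd, probes_min = as.integer(probes_min),
               probes_max = as.integer(probes_max), attenuation = attenuation,
               probe_offset_sd = probe_offset_sd,
               n_decoy_sets = as.integer(n_decoy_sets),
               decoy_size = as.integer(decoy_size),
               n_drugs = as.integer(n_drugs), n_lines = as.integer(n_lines),
               n_coupled = as.integer(n_coupled), coupling_sd = coupling_sd,
               slope = slope, response_sd = response_sd,
               baseline_hazard = baseline_hazard, log_hr = log_hr,
               censoring_rate = censoring_rate)
  with(spec, {
    stopifnot(n_genes >= 1L, n_groups >= 1L, replicates >= 1L,
              probes_min >= 1L, probes_max >= probes_min,
              n_drugs >= 1L, n_lines >= 1L,
              noise_sd > 0, baseline_hazard > 0,
              censoring_rate >= 0, censoring_rate < 1)
  })
  sizes <- vapply(spec$signatures, function(s) as.integer(s$size), integer(1))
  if (sum(sizes) > spec$n_genes)
    stop("signature sizes (", sum(sizes), ") exceed n_genes (", spec$n_genes, ")")
  if (spec$n_coupled > spec$n_genes)
    stop("n_coupled exceeds n_genes")
  structure(spec, class = "SyntheticSpec")
}

sig_shifts <- function(sig, n_groups) {
  if (!is.null(sig$shifts)) {
    if (length(sig$shifts) != n_groups)
      stop("explicit shifts must have length n_groups")
    return(as.numeric(sig$shifts))
  }
  delta <- if (is.null(sig$delta)) 1 else sig$delta
  delta * (n_groups - seq_len(n_groups))  # group 1 strongest, spacing delta
}

#' Generate a replicate-structured expression compendium with planted signal
#'
#' Gene-level truth: per-gene baseline + the signature's per-group mean shift
#' (for signature genes) + Gaussian replicate noise. Each gene is then
#' expanded into 2-4 probe sets: one "informative" probe reproduces the gene
#' profile; the others carry only `attenuation` of the signal plus jitter, so
#' their SD across samples is lower and the max-SD collapse rule is exercised
#' non-trivially.
#'
#' @param spec a [synthetic_spec()]
#' @return list with `expr` (probe-level `ExpressionMatrix`), `gene_level`
#'   (the gene-level `ExpressionMatrix` before probe expansion), `grouping`,
#'   `probe_map`, `sets` (planted signatures plus decoys), and `truth`
#'   (planted per-signature group ordering, shift matrix, memberships)
#' @export
generate_expression_compendium <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  groups <- sprintf("G%02d", seq_len(spec$n_groups))
  samples <- as.vector(t(outer(groups, seq_len(spec$replicates),
                               function(g, r) paste0(g, "_r", r))))
  grp_of <- rep(groups, each = spec$replicates)
  baseline <- stats::rnorm(spec$n_genes, spec$baseline_mean, spec$baseline_sd)
  shift <- matrix(0, spec$n_genes, spec$n_groups,
                  dimnames = list(genes, groups))
  sets <- list()
  truth_order <- list()
  next_gene <- 1L
  for (nm in names(spec$signatures)) {
    sig <- spec$signatures[[nm]]
    idx <- next_gene:(next_gene + sig$size - 1L)
    next_gene <- next_gene + sig$size
    sh <- sig_shifts(sig, spec$n_groups)
    shift[idx, ] <- matrix(sh, length(idx), spec$n_groups, byrow = TRUE)
    sets[[nm]] <- genes[idx]
    truth_order[[nm]] <- groups[order(-sh, seq_along(sh))]
  }
  signal <- baseline + shift[, match(grp_of, groups), drop = FALSE]
  gene_vals <- signal + matrix(stats::rnorm(length(signal), 0, spec$noise_sd),
                               nrow = spec$n_genes)
  dimnames(gene_vals) <- list(genes, samples)
  # probe expansion: probe 1 informative, others attenuated + jittered
  n_probes <- sample(spec$probes_min:spec$probes_max, spec$n_genes,
                     replace = TRUE)
  gene_rep <- rep(seq_len(spec$n_genes), n_probes)
  probe_rank <- sequence(n_probes)
  probe_ids <- sprintf("%s_p%d", genes[gene_rep], probe_rank)
  centered <- gene_vals - baseline
  probe_vals <- matrix(NA_real_, length(probe_ids), length(samples),
                       dimnames = list(probe_ids, samples))
  informative <- probe_rank == 1L
  probe_vals[informative, ] <- gene_vals[gene_rep[informative], , drop = FALSE]
  att <- which(!informative)
  probe_vals[att, ] <- baseline[gene_rep[att]] +
    spec$attenuation * centered[gene_rep[att], , drop = FALSE] +
    matrix(stats::rnorm(length(att) * length(samples), 0, spec$probe_offset_sd),
           nrow = length(att))
  if (spec$n_decoy_sets > 0L)
    for (i in seq_len(spec$n_decoy_sets))
      sets[[sprintf("decoy%02d", i)]] <- sample(genes, spec$decoy_size)
  list(expr = expression_matrix(probe_vals, "probe"),
       gene_level = expression_matrix(gene_vals, "gene"),
       grouping = sample_grouping(stats::setNames(grp_of, samples)),
       probe_map = stats::setNames(genes[gene_rep], probe_ids),
       sets = gene_set_collection(sets),
       truth = list(ordering = truth_order, shifts = shift,
                    signature_genes = sets[names(spec$signatures)]))
}

#' Generate a -log(GI50) matrix coupled to expression
#'
#' Draws a latent per-line sensitivity factor `u`, injects it into
#' `n_coupled` randomly chosen genes of the supplied gene-level matrix
#' (+u for the positive half, -u for the negative half; without this shared
#' factor no individual gene could reach the |r| > 0.5 selection threshold),
#' and sets each drug's response to `slope` times the signed mean of the
#' coupled genes' centered expression plus Gaussian noise.
#'
#' @param spec a [synthetic_spec()]
#' @param expr gene-level `ExpressionMatrix` whose columns are the cell
#'   lines (>= 2)
#' @return list with `response` (drugs x lines matrix of -log GI50), `expr`
#'   (the expression matrix with the coupling injected) and `truth`
#'   (`positive` / `negative` gene vectors and the latent factor `u`)
#' @export
generate_gi50_matrix <- function(spec, expr) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  expr <- as_expression_matrix(expr)
  v <- expr$values
  if (ncol(v) < 2L)
    stop("need >= 2 cell lines (correlation undefined on a single line)")
  if (spec$n_coupled > nrow(v))
    stop("n_coupled exceeds the number of genes in the matrix")
  set.seed(spec$seed + 1L)
  coupled <- sample(rownames(v), spec$n_coupled)
  n_pos <- ceiling(spec$n_coupled / 2)
  pos <- sort(coupled[seq_len(n_pos)])
  neg <- sort(coupled[-seq_len(n_pos)])
  u <- stats::rnorm(ncol(v), 0, spec$coupling_sd)
  v[pos, ] <- v[pos, , drop = FALSE] + rep(u, each = length(pos))
  v[neg, ] <- v[neg, , drop = FALSE] - rep(u, each = length(neg))
  centered <- v - rowMeans(v)
  sgn <- stats::setNames(rep(c(1, -1), c(length(pos), length(neg))),
                         c(pos, neg))
  s <- colMeans(centered[c(pos, neg), , drop = FALSE] * sgn[c(pos, neg)])
  response <- matrix(rep(spec$slope * s, each = spec$n_drugs),
                     nrow = spec$n_drugs) +
    matrix(stats::rnorm(spec$n_drugs * ncol(v), 0, spec$response_sd),
           nrow = spec$n_drugs)
  dimnames(response) <- list(sprintf("NSC%04d", seq_len(spec$n_drugs)),
                             colnames(v))
  list(response = response,
       expr = expression_matrix(v, "gene"),
       truth = list(positive = pos, negative = neg, u = u))
}

#' Generate a survival cohort whose hazard depends on a signature score
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(log_hr * score)`; censoring times are independent
#' exponentials with rate chosen so that roughly `censoring_rate` of a
#' zero-score cohort is censored (`censoring_rate = 0` disables censoring).
#'
#' @param spec a [synthetic_spec()]
#' @param scores per-patient signature scores
#' @return a [survival_cohort()]
#' @export
generate_survival_cohort <- function(spec, scores) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed + 2L)
  n <- length(scores)
  rate <- spec$baseline_hazard * exp(spec$log_hr * scores)
  t_event <- stats::rexp(n, rate)
  if (spec$censoring_rate > 0) {
    rate_c <- spec$baseline_hazard *
      spec$censoring_rate / (1 - spec$censoring_rate)
    t_cens <- stats::rexp(n, rate_c)
  } else {
    t_cens <- rep(Inf, n)
  }
  survival_cohort(time = pmin(t_event, t_cens),
                  event = as.integer(t_event <= t_cens),
                  score = scores)
}

#' Write all synthetic fixtures of a spec to a directory
#'
#' Emits the probe-level expression TSV, sample-group TSV, probe map, GMT of
#' planted sets, -log(GI50) TSV, survival cohort TSV and a `truth.json`
#' sufficient to score every pipeline stage's recovery.
#'
#' @param spec a [synthetic_spec()]
#' @param out_dir output directory (created if absent)
#' @return invisibly, the named vector of written paths
#' @export
write_synthetic_fixtures <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  comp <- generate_expression_compendium(spec)
  gi <- generate_gi50_matrix(spec, comp$gene_level)
  score <- colMeans(center_genes(comp$gene_level)$values[
    comp$truth$signature_genes[[1L]], , drop = FALSE])
  coh <- generate_survival_cohort(spec, score)
  paths <- c(expr = file.path(out_dir, "expression.tsv"),
             groups = file.path(out_dir, "groups.tsv"),
             probe_map = file.path(out_dir, "probe_map.tsv"),
             gmt = file.path(out_dir, "sets.gmt"),
             gi50 = file.path(out_dir, "gi50_neglog.tsv"),
             cohort = file.path(out_dir, "cohort.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_expression_matrix(comp$expr, paths[["expr"]])
  write_sample_grouping(comp$grouping, paths[["groups"]])
  write_probe_map(comp$probe_map, paths[["probe_map"]])
  write_gmt(comp$sets, paths[["gmt"]])
  write_gi50_matrix(gi$response, paths[["gi50"]])
  write_survival_cohort(coh, paths[["cohort"]])
  jsonlite::write_json(
    list(seed = spec$seed,
         ordering = comp$truth$ordering,
         signature_genes = comp$truth$signature_genes,
         gi50_positive = gi$truth$positive,
         gi50_negative = gi$truth$negative,
         log_hr = spec$log_hr),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
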