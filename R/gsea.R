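#' Rank genes of one group against a reference panel
#'
#' Per-gene metric = mean over the target group's replicates minus the mean
#' over the pooled reference samples (log2 difference). The list is sorted by
#' decreasing metric, ties broken by gene symbol so the ordering is
#' deterministic even in the all-zero degenerate case.
#'
#' @param m gene-level `ExpressionMatrix`
#' @param grouping a [sample_grouping()]
#' @param target group to profile
#' @param reference_groups character vector of reference group labels whose
#'   samples are pooled
#' @return a `RankedGeneList`: data.frame with columns `gene`, `metric`,
#'   sorted by non-increasing metric
#' @export
rank_genes_vs_reference <- function(m, grouping, target, reference_groups) {
  m <- as_expression_matrix(m)
  gl <- group_labels_for(m, grouping)
  if (!target %in% gl$levels) stop("target group not present: ", target)
  refs <- gl$per_sample %in% reference_groups
  if (!any(refs)) stop("empty reference pool: none of ",
                       paste(reference_groups, collapse = ", "), " present")
  metric <- rowMeans(m$values[, gl$per_sample == target, drop = FALSE]) -
    rowMeans(m$values[, refs, drop = FALSE])
  ord <- order(-metric, rownames(m$values), method = "radix")
  structure(data.frame(gene = rownames(m$values)[ord],
                       metric = unname(metric[ord]),
                       stringsAsFactors = FALSE),
            class = c("RankedGeneList", "data.frame"))
}

ranked_gene_list <- function(genes, metric) {
  if (anyDuplicated(genes)) stop("ranked list genes must be unique")
  if (is.unsorted(rev(metric))) stop("ranking metric must be non-increasing")
  structure(data.frame(gene = as.character(genes), metric = as.numeric(metric),
                       stringsAsFactors = FALSE),
            class = c("RankedGeneList", "data.frame"))
}

# weights used by the running sum: |metric|^p, with a fall-back to equal
# weights when all metrics are zero (e.g. ranking a group against itself)
es_weights <- function(metric, weight_exponent) {
  w <- abs(metric)^weight_exponent
  if (sum(w) == 0) rep(1, length(w)) else w
}

# enrichment score from sorted hit positions only, O(|set|): the running-sum
# maximum occurs at a hit, the minimum just before one (after the last hit
# the sum decays monotonically to 0). `w` = weights of the whole list.
es_from_positions <- function(pos, w, N) {
  k <- length(pos)
  wh <- w[pos]
  sw <- sum(wh)
  if (sw == 0) wh <- rep(1 / k, k) else wh <- wh / sw
  cumhit <- cumsum(wh)
  miss <- (pos - seq_len(k)) / (N - k)
  top <- cumhit - miss
  bottom <- c(0, cumhit[-k]) - miss
  mx <- max(top)
  mn <- min(bottom)
  if (mx >= abs(mn)) mx else mn
}

#' GSEA enrichment score and running-sum profile
#'
#' Weighted Kolmogorov-Smirnov-style statistic: walking down the ranked
#' list, set members ("hits") increment the running sum by their weight
#' `|metric|^p` normalized over hits, non-members decrement it by
#' `1/(N - Nh)`. The enrichment score is the signed maximum deviation of the
#' profile from zero (positive preferred on an exact tie of magnitudes).
#'
#' @param ranked a `RankedGeneList` (see [rank_genes_vs_reference()])
#' @param set character vector of gene symbols
#' @param weight_exponent the exponent p; `0` gives the classical
#'   equal-weight statistic, `1` (default) the standard weighted form
#' @return list with `es`, the full `running_sum` profile (length N) and the
#'   `hit_indices`
#' @export
enrichment_score <- function(ranked, set, weight_exponent = 1) {
  genes <- ranked$gene
  metric <- ranked$metric
  N <- length(genes)
  hits <- genes %in% set
  Nh <- sum(hits)
  if (Nh == 0L) stop("gene set does not intersect the ranked list")
  if (Nh == N) stop("gene set covers the entire ranked list")
  w <- es_weights(metric, weight_exponent)
  inc <- rep(-1 / (N - Nh), N)
  wh <- w[hits]
  if (sum(wh) == 0) wh <- rep(1, Nh)
  inc[hits] <- wh / sum(wh)
  rs <- cumsum(inc)
  mx <- max(rs)
  mn <- min(rs)
  es <- if (mx >= abs(mn)) mx else mn
  list(es = es, running_sum = rs, hit_indices = which(hits))
}

#' GSEA of one set with a gene-set-resampling null
#'
#' The null distribution is built by drawing `n_resamples` random gene sets
#' of the same cardinality as `set` intersected with the list, uniformly from
#' the ranked list's genes (without replacement by default; `replace = TRUE`
#' draws a bootstrap sample whose duplicates are collapsed). The p-value uses
#' the add-one estimator over same-sign null scores, so it is never exactly
#' zero; NES = ES divided by the mean magnitude of same-sign null scores.
#'
#' @inheritParams enrichment_score
#' @param n_resamples number of null gene sets (>= 100)
#' @param seed integer seed; the same seed gives a bit-identical result
#' @param replace draw null sets with replacement (collapsing duplicates)
#' @param set_name label carried into the result
#' @return object of class `EnrichmentResult`: list with `set`, `size`, `es`,
#'   `nes`, `p_value`, `fdr` (NA for a single set; see
#'   [gsea_two_condition()]), `n_null`, `unstable`, and the `null_es` vector
#' @export
gsea_with_geneset_null <- function(ranked, set, n_resamples = 1000,
                                   seed = NULL, weight_exponent = 1,
                                   replace = FALSE, set_name = "set") {
  if (n_resamples < 100L) stop("n_resamples must be >= 100")
  obs <- enrichment_score(ranked, set, weight_exponent)
  N <- nrow(ranked)
  k <- length(obs$hit_indices)
  w <- es_weights(ranked$metric, weight_exponent)
  if (!is.null(seed)) set.seed(seed)
  null_es <- vapply(seq_len(n_resamples), function(b) {
    pos <- sample.int(N, k, replace = replace)
    if (replace) pos <- unique(pos)
    es_from_positions(sort.int(pos, method = "radix"), w, N)
  }, numeric(1))
  same <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  unstable <- length(same) == 0L
  if (unstable) {
    warning("no same-sign null scores for '", set_name,
            "'; p-value at resolution limit, NES unstable")
    p <- 1 / (n_resamples + 1)
    nes <- NA_real_
  } else {
    p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    nes <- obs$es / mean(abs(same))
  }
  structure(list(set = set_name, size = k, es = obs$es, nes = nes,
                 p_value = p, fdr = NA_real_, n_null = n_resamples,
                 unstable = unstable, null_es = null_es),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult '%s': size %d, ES %.3f, NES %.3f, p %.4g\n",
              x$set, x$size, x$es, x$nes, x$p_value))
  invisible(x)
}

# Subramanian-style FDR from pooled sign-normalized null scores: for each
# observed NES*, q = (tail fraction of pooled same-sign normalized nulls)
# / (tail fraction of observed same-sign NES), capped at 1.
gsea_fdr <- function(results) {
  norm_nulls <- unlist(lapply(results, function(r) {
    pos <- r$null_es[r$null_es >= 0]
    neg <- r$null_es[r$null_es < 0]
    c(if (length(pos)) pos / mean(pos),
      if (length(neg)) neg / mean(-neg))  # sign kept, unit mean magnitude
  }))
  obs <- vapply(results, function(r) r$nes, numeric(1))
  vapply(seq_along(results), function(i) {
    nes <- obs[[i]]
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      pool <- norm_nulls[norm_nulls >= 0]
      num <- if (length(pool)) mean(pool >= nes) else 0
      den <- mean(obs >= nes, na.rm = TRUE)
    } else {
      pool <- norm_nulls[norm_nulls < 0]
      num <- if (length(pool)) mean(pool <= nes) else 0
      den <- mean(obs <= nes, na.rm = TRUE)
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))
}

#' Two-condition GSEA over a gene-set collection
#'
#' Ranks genes by the mean log2 difference between two groups
#' (`cond_a - cond_b`), evaluates every set of the collection with the
#' gene-set-resampling null, attaches pooled-null FDR q-values and sorts by
#' decreasing NES. Each set gets its own deterministic sub-seed derived from
#' `seed`, so results do not depend on collection order.
#'
#' @param m gene-level `ExpressionMatrix`
#' @param grouping a [sample_grouping()]
#' @param cond_a,cond_b group labels to contrast
#' @param sets named list of gene sets
#' @param n_resamples,seed,weight_exponent,replace passed to
#'   [gsea_with_geneset_null()]
#' @return data.frame with columns `set`, `size`, `es`, `nes`, `p_value`,
#'   `fdr`, sorted by decreasing NES
#' @export
gsea_two_condition <- function(m, grouping, cond_a, cond_b, sets,
                               n_resamples = 1000, seed = NULL,
                               weight_exponent = 1, replace = FALSE) {
  if (!length(sets))
    return(data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p_value = numeric(0), fdr = numeric(0)))
  ranked <- rank_genes_vs_reference(m, grouping, cond_a, cond_b)
  results <- lapply(seq_along(sets), function(i)
    gsea_with_geneset_null(ranked, sets[[i]], n_resamples = n_resamples,
                           seed = if (is.null(seed)) NULL else seed + i,
                           weight_exponent = weight_exponent,
                           replace = replace, set_name = names(sets)[[i]]))
  fdr <- gsea_fdr(results)
  out <- data.frame(set = vapply(results, `[[`, character(1), "set"),
                    size = vapply(results, `[[`, integer(1), "size"),
                    es = vapply(results, `[[`, numeric(1), "es"),
                    nes = vapply(results, `[[`, numeric(1), "nes"),
                    p_value = vapply(results, `[[`, numeric(1), "p_value"),
                    fdr = fdr, stringsAsFactors = FALSE)
  out[order(-out$nes, out$set), , drop = FALSE]
}
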