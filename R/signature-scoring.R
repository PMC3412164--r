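#' Gene-wise zero-centering across all samples
#'
#' Subtracts from every gene its mean across *all* samples of the compendium
#' (not per group). Scores downstream are therefore relative expression: a
#' positive signature score means the group expresses the set above the
#' compendium average. Note the consequence, stated loudly: changing which
#' samples make up the compendium changes every score.
#'
#' @param m gene-level `ExpressionMatrix` (or plain named matrix)
#' @return centered `ExpressionMatrix`; every row has mean 0
#' @export
center_genes <- function(m) {
  m <- as_expression_matrix(m)
  if (m$level != "gene") stop("center_genes expects a gene-level matrix")
  expression_matrix(m$values - rowMeans(m$values), "gene")
}

#' Score one gene set per replicate group
#'
#' Per sample, the score is the mean of the centered expression of the set's
#' genes present in the matrix; per group, the mean of its replicate samples'
#' scores (so groups with 2 and 3 replicates are comparable). Set genes
#' absent from the matrix are dropped with a warning; an empty intersection
#' is an error.
#'
#' @param centered gene-wise centered `ExpressionMatrix` (see [center_genes()])
#' @param genes character vector of gene symbols
#' @param grouping a [sample_grouping()] covering every sample of the matrix
#' @param set_name label used in messages
#' @return named numeric vector of group scores (groups in order of first
#'   appearance), with attribute `sample_scores`
#' @export
score_gene_set <- function(centered, genes, grouping, set_name = "gene set") {
  m <- as_expression_matrix(centered)
  gl <- group_labels_for(m, grouping)
  present <- intersect(genes, rownames(m$values))
  if (!length(present))
    stop("no gene of '", set_name, "' is present in the expression matrix")
  n_missing <- length(unique(genes)) - length(present)
  if (n_missing > 0L)
    warning(sprintf("'%s': %d gene(s) absent from the matrix; scoring the %d present",
                    set_name, n_missing, length(present)))
  sample_scores <- colMeans(m$values[present, , drop = FALSE])
  group_scores <- vapply(gl$levels, function(g)
    mean(sample_scores[gl$per_sample == g]), numeric(1))
  structure(stats::setNames(group_scores, gl$levels),
            sample_scores = sample_scores)
}

#' Build the signature score and rank table
#'
#' For every gene set of the collection, scores each replicate group
#' ([score_gene_set()]) and converts each signature column to ranks:
#' rank 1 = highest set-average centered expression ("strongest signature").
#' Ties are broken by group order (order of first appearance in the
#' grouping), so the table is deterministic.
#'
#' @param centered gene-wise centered `ExpressionMatrix`
#' @param sets named list of gene sets ([gene_set_collection()])
#' @param grouping a [sample_grouping()]
#' @return object of class `RankTable`: list with `scores` and `ranks`
#'   (groups x signatures matrices), `groups`, `signatures`
#' @export
build_rank_table <- function(centered, sets, grouping) {
  if (!length(sets)) stop("empty gene-set collection")
  m <- as_expression_matrix(centered)
  gl <- group_labels_for(m, grouping)
  scores <- vapply(names(sets), function(s)
    as.numeric(score_gene_set(m, sets[[s]], grouping, set_name = s)),
    numeric(length(gl$levels)))
  scores <- matrix(scores, nrow = length(gl$levels),
                   dimnames = list(gl$levels, names(sets)))
  ranks <- apply(scores, 2L, function(s) {
    r <- integer(length(s))
    r[order(-s, seq_along(s))] <- seq_along(s)
    r
  })
  ranks <- matrix(as.integer(ranks), nrow = nrow(scores),
                  dimnames = dimnames(scores))
  structure(list(scores = scores, ranks = ranks,
                 groups = gl$levels, signatures = names(sets)),
            class = "RankTable")
}

#' @export
print.RankTable <- function(x, ...) {
  cat(sprintf("RankTable: %d group(s) x %d signature(s)\n",
              length(x$groups), length(x$signatures)))
  print(x$ranks)
  invisible(x)
}

#' Write a rank table (or its scores) as TSV
#'
#' Layout mirrors the published table: rows = groups, columns = signatures.
#' @param rt a `RankTable`
#' @param path output path
#' @param what `"ranks"` or `"scores"`
#' @export
write_rank_table <- function(rt, path, what = c("ranks", "scores")) {
  what <- match.arg(what)
  v <- rt[[what]]
  d <- data.frame(group = rownames(v), v, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive a fold-change gene signature within a gene family
#'
#' Rule used for the small-intestine solute-carrier signature: keep genes
#' whose symbol starts with a family prefix (e.g. `"SLC"`) and whose mean
#' log2 expression in the target group exceeds the reference group by at
#' least `log2(min_fold)`.
#'
#' @param m gene-level `ExpressionMatrix` on log2 scale
#' @param grouping a [sample_grouping()]
#' @param target,reference group labels
#' @param family_prefix gene-symbol prefix filter (e.g. `"SLC"`)
#' @param min_fold minimum fold change on the linear scale (default 2,
#'   i.e. >= 1 log2 unit)
#' @return character vector of gene symbols (possibly empty, with a warning
#'   if no gene matches the prefix)
#' @export
derive_fold_change_signature <- function(m, grouping, target, reference,
                                         family_prefix, min_fold = 2) {
  m <- as_expression_matrix(m)
  gl <- group_labels_for(m, grouping)
  for (g in c(target, reference))
    if (!g %in% gl$levels) stop("group not present in matrix: ", g)
  fam <- rownames(m$values)[startsWith(rownames(m$values), family_prefix)]
  if (!length(fam)) {
    warning("no gene matches prefix '", family_prefix, "'")
    return(character(0))
  }
  tmean <- rowMeans(m$values[fam, gl$per_sample == target, drop = FALSE])
  rmean <- rowMeans(m$values[fam, gl$per_sample == reference, drop = FALSE])
  sort(fam[tmean - rmean >= log2(min_fold)])
}

#' Principal component analysis of sample profiles
#'
#' PCA of the samples after gene-wise centering, optionally restricted to a
#' feature subset (e.g. all solute-carrier genes). Components with null
#' variance are dropped; each retained loading vector is scaled so that its
#' largest-magnitude entry is positive, fixing the sign indeterminacy.
#'
#' @param m `ExpressionMatrix` (>= 2 samples)
#' @param feature_filter optional character vector restricting the features
#'   used; an empty intersection is an error
#' @return object of class `PCAResult`: list with `loadings`
#'   (features x components), `scores` (samples x components) and
#'   `var_explained` (non-increasing, sums to <= 1)
#' @export
pca_project <- function(m, feature_filter = NULL) {
  m <- as_expression_matrix(m)
  v <- m$values
  if (ncol(v) < 2L) stop("PCA needs >= 2 samples")
  if (!is.null(feature_filter)) {
    keep <- intersect(feature_filter, rownames(v))
    if (!length(keep)) stop("feature filter eliminates every row of the matrix")
    v <- v[keep, , drop = FALSE]
  }
  p <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  tot <- sum(p$sdev^2)
  keep <- which(p$sdev > max(p$sdev) * 1e-8)
  load <- p$rotation[, keep, drop = FALSE]
  sc <- p$x[, keep, drop = FALSE]
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      sc[, j] <- -sc[, j]
    }
  }
  structure(list(loadings = load, scores = sc,
                 var_explained = p$sdev[keep]^2 / tot),
            class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  cat(sprintf("PCAResult: %d component(s); variance explained: %s\n",
              ncol(x$scores),
              paste(sprintf("%.3f", x$var_explained), collapse = ", ")))
  invisible(x)
}
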