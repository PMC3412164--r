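#' Read a drugs x cell-lines GI50 matrix
#'
#' TSV with drug identifiers (e.g. NSC numbers) in the first column and cell
#' lines in the header. Unless `already_neglog` is set, values are molar GI50
#' concentrations and are transformed to `-log10(GI50)` so that larger means
#' more sensitive. Empty cells or `NA` are kept as missing.
#'
#' @param path file path
#' @param already_neglog values are already -log(GI50)
#' @param log_base logarithm base for the transform (default 10, the NCI
#'   convention for molar GI50 data)
#' @return numeric matrix drugs x cell lines, possibly with `NA`
#' @export
read_gi50_matrix <- function(path, already_neglog = FALSE, log_base = 10) {
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                         row.names = 1L)
  v <- as.matrix(d)
  storage.mode(v) <- "double"
  if (!already_neglog) {
    if (any(v <= 0, na.rm = TRUE))
      stop("GI50 concentrations must be positive for the -log transform")
    v <- -log(v, base = log_base)
  }
  if (any(is.infinite(v), na.rm = TRUE))
    stop("non-finite -log(GI50) values in ", path)
  v
}

#' Write a -log(GI50) matrix as TSV
#' @param d numeric matrix drugs x cell lines
#' @param path output path
#' @export
write_gi50_matrix <- function(d, path) {
  out <- data.frame(drug_id = rownames(d), d, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter the drug panel for completeness and variability
#'
#' Retains drugs with a -log(GI50) value in every cell line (if
#' `require_complete`) and with standard deviation above `min_sd` across the
#' lines (default 0: constant drugs carry no ranking information).
#'
#' @param d numeric matrix drugs x cell lines (-log GI50)
#' @param require_complete drop drugs with any missing line
#' @param min_sd strict lower bound on the per-drug SD
#' @return the filtered matrix (removals reported via `message`)
#' @export
filter_drug_panel <- function(d, require_complete = TRUE, min_sd = 0) {
  complete <- rowSums(is.na(d)) == 0L
  sds <- apply(d, 1L, stats::sd, na.rm = TRUE)
  keep <- (!require_complete | complete) & !is.na(sds) & sds > min_sd
  if (!any(keep)) stop("no drug passes the panel filter")
  removed <- sum(!keep)
  if (removed > 0L)
    message(sprintf("filter_drug_panel: removed %d of %d drug(s)",
                    removed, nrow(d)))
  d[keep, , drop = FALSE]
}

#' Gene-by-drug correlation profiles
#'
#' Correlates each gene's log2 expression with each drug's -log(GI50) across
#' the cell lines shared by the two matrices. Pairwise-complete observations
#' are used; any pair with fewer than `min_obs` complete lines, and any
#' constant gene or drug vector, yields `NA` (with a warning for constant
#' genes).
#'
#' @param expr gene-level `ExpressionMatrix` (columns = cell lines)
#' @param d numeric matrix drugs x cell lines of -log(GI50)
#' @param method `"pearson"` (default; log2 expression vs -log GI50) or
#'   `"spearman"`
#' @param min_obs minimum complete observations per pair (default 3)
#' @return genes x drugs matrix of correlation coefficients in `[-1, 1]`
#' @export
gene_drug_correlations <- function(expr, d, method = c("pearson", "spearman"),
                                   min_obs = 3L) {
  method <- match.arg(method)
  expr <- as_expression_matrix(expr)
  shared <- intersect(sample_ids(expr), colnames(d))
  if (length(shared) < min_obs)
    stop("need >= ", min_obs, " shared cell lines; expression has [",
         paste(sample_ids(expr), collapse = ", "), "], GI50 has [",
         paste(colnames(d), collapse = ", "), "]")
  x <- t(expr$values[, shared, drop = FALSE])    # lines x genes, complete
  y <- t(d[, shared, drop = FALSE])              # lines x drugs, may have NA
  r <- suppressWarnings(stats::cor(x, y, use = "pairwise.complete.obs",
                                   method = method))
  n_obs <- crossprod(matrix(1, nrow(x), ncol(x)), !is.na(y))
  r[n_obs < min_obs] <- NA_real_
  const_gene <- apply(x, 2L, function(v) stats::sd(v) == 0)
  if (any(const_gene)) {
    warning(sum(const_gene), " constant gene row(s): correlations undefined")
    r[const_gene, ] <- NA_real_
  }
  r
}

#' Select genes correlated with drug response
#'
#' The published rule: a gene is kept when its correlation with -log(GI50)
#' exceeds the threshold in absolute value (strict inequality) for at least
#' `min_drugs` compounds.
#'
#' @param cmat genes x drugs correlation matrix
#'   (see [gene_drug_correlations()])
#' @param threshold absolute-correlation threshold in (0, 1); default 0.5
#' @param min_drugs minimum number of exceeding drugs; default 3
#' @return character vector of selected gene symbols
#' @export
select_correlated_genes <- function(cmat, threshold = 0.5, min_drugs = 3L) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (min_drugs < 1L) stop("min_drugs must be >= 1")
  n_hit <- rowSums(abs(cmat) > threshold, na.rm = TRUE)
  rownames(cmat)[n_hit >= min_drugs]
}

#' Split selected genes into response-positive / response-negative signatures
#'
#' Average-linkage hierarchical clustering of the genes' correlation
#' profiles, with distance 1 - r (centered Pearson correlation) or
#' 1 - Spearman rank correlation; the tree is cut at its root into exactly
#' two clusters. The cluster with the larger mean profile value is labeled
#' positive (genes whose high expression accompanies sensitivity), the other
#' negative.
#'
#' @param cmat genes x drugs correlation matrix restricted to selected genes
#'   (>= 2 rows)
#' @param linkage only `"average"` is supported
#' @param distance `"centered_correlation"` or `"spearman"`
#' @return object of class `ResponseSignaturePair`: list with `positive` and
#'   `negative` gene vectors (disjoint), `median_correlation` (2 x drugs
#'   matrix of per-cluster per-drug medians), and the `cluster` assignment
#' @export
split_response_signatures <- function(cmat,
                                      linkage = "average",
                                      distance = c("centered_correlation",
                                                   "spearman")) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  if (nrow(cmat) < 2L) stop("need >= 2 selected genes to split")
  method <- if (distance == "spearman") "spearman" else "pearson"
  cors <- suppressWarnings(stats::cor(t(cmat), method = method,
                                      use = "pairwise.complete.obs"))
  if (anyNA(cors))
    stop("undefined gene-gene profile correlations (constant or disjoint profiles); filter first")
  dd <- stats::as.dist(1 - cors)
  if (all(dd < 1e-12))
    stop("all correlation profiles are identical; no two-cluster structure")
  hc <- stats::hclust(dd, method = linkage)
  cl <- stats::cutree(hc, k = 2L)
  m1 <- mean(cmat[cl == 1L, , drop = FALSE], na.rm = TRUE)
  m2 <- mean(cmat[cl == 2L, , drop = FALSE], na.rm = TRUE)
  pos_id <- if (m1 >= m2) 1L else 2L
  pos <- sort(rownames(cmat)[cl == pos_id])
  neg <- sort(rownames(cmat)[cl != pos_id])
  med <- rbind(
    positive = apply(cmat[pos, , drop = FALSE], 2L, stats::median, na.rm = TRUE),
    negative = apply(cmat[neg, , drop = FALSE], 2L, stats::median, na.rm = TRUE))
  structure(list(positive = pos, negative = neg,
                 median_correlation = med, cluster = cl),
            class = "ResponseSignaturePair")
}

#' @export
print.ResponseSignaturePair <- function(x, ...) {
  cat(sprintf("ResponseSignaturePair: %d positive, %d negative gene(s)\n",
              length(x$positive), length(x$negative)))
  invisible(x)
}

#' Median correlation of a gene set, per drug and overall
#'
#' Summarizes a signature's association with drug response: the median over
#' the set's genes of the correlation coefficient, per drug, and the median
#' of those per-drug values overall. Medians of even-sized samples are the
#' mean of the two middle values (the [stats::median()] convention).
#'
#' @param cmat genes x drugs correlation matrix
#' @param set character vector of gene symbols
#' @return list with `per_drug` (named numeric) and `overall` (scalar)
#' @export
median_set_correlation <- function(cmat, set) {
  present <- intersect(set, rownames(cmat))
  if (!length(present)) stop("gene set does not intersect the correlation matrix")
  per_drug <- apply(cmat[present, , drop = FALSE], 2L, stats::median,
                    na.rm = TRUE)
  list(per_drug = per_drug, overall = stats::median(per_drug, na.rm = TRUE))
}

#' Associate a signature's rank order with drug response
#'
#' For one signature column of a rank table restricted to a cell-line panel:
#' per drug, the Spearman correlation between the signature ranks and
#' -log(GI50) across the shared lines. The resulting per-drug distribution
#' is what response-association boxplots summarize. A negative value means
#' stronger signature (rank 1 = strongest) goes with higher sensitivity.
#'
#' @param ranks named numeric/integer vector, cell line -> signature rank
#' @param d numeric matrix drugs x cell lines of -log(GI50)
#' @param min_obs minimum shared observations per drug (default 3)
#' @return named numeric vector, one Spearman correlation per drug (`NA`
#'   where fewer than `min_obs` lines have a response value)
#' @export
rank_response_association <- function(ranks, d, min_obs = 3L) {
  shared <- intersect(names(ranks), colnames(d))
  if (length(shared) < min_obs)
    stop("need >= ", min_obs, " shared cell lines between ranks and GI50 matrix")
  r <- ranks[shared]
  vapply(rownames(d), function(drug) {
    y <- d[drug, shared]
    ok <- !is.na(y)
    if (sum(ok) < min_obs) return(NA_real_)
    suppressWarnings(stats::cor(r[ok], y[ok], method = "spearman"))
  }, numeric(1))
}
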