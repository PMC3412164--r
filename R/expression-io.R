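#' Construct an expression matrix
#'
#' The central container of the package: a dense numeric matrix of log2
#' expression values, rows = features (probe sets or gene symbols),
#' columns = samples, together with a declared summarization level.
#'
#' Missing or non-finite values are rejected outright: summarized microarray
#' matrices are complete, and an explicit error is clearer than silent
#' imputation.
#'
#' @param values numeric matrix with row and column names; rows are features,
#'   columns are samples, values are log2 intensities.
#' @param level `"gene"` or `"probe"`. At gene level duplicate feature ids are
#'   an error; at probe level several probe sets may later collapse to one
#'   gene via [collapse_probes_max_sd()].
#' @return an object of class `ExpressionMatrix` (a list with elements
#'   `values` and `level`).
#' @seealso [read_expression_matrix()], [quantile_normalize()],
#'   [collapse_probes_max_sd()], [center_genes()]
#' @export
expression_matrix <- function(values, level = c("gene", "probe")) {
  level <- match.arg(level)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix requires feature (row) and sample (column) names")
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  if (level == "gene") {
    dupg <- rownames(values)[duplicated(rownames(values))]
    if (length(dupg))
      stop("duplicate gene id(s) at gene level: ",
           paste(unique(dupg), collapse = ", "))
  }
  if (!all(is.finite(values)))
    stop("expression values must be finite; impute or filter missing values first")
  structure(list(values = values, level = level), class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
as.matrix.ExpressionMatrix <- function(x, ...) x$values

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d %s-level features x %d samples\n",
              nrow(x$values), x$level, ncol(x$values)))
  invisible(x)
}

#' Feature and sample identifiers of an expression matrix
#' @param m an `ExpressionMatrix`
#' @return character vector of ids
#' @export
feature_ids <- function(m) rownames(as_expression_matrix(m)$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(m) colnames(as_expression_matrix(m)$values)

# Accept either an ExpressionMatrix or a plain named matrix in every
# operation; plain matrices are assumed gene-level unless told otherwise.
as_expression_matrix <- function(m, level = "gene") {
  if (inherits(m, "ExpressionMatrix")) m else expression_matrix(m, level)
}

#' Construct / validate a sample-to-group mapping
#'
#' A named character vector: names are sample ids, values are group labels
#' (replicate groups such as cell lines or tissue pools). Group order is the
#' order of first appearance and is preserved by every downstream table.
#'
#' @param x named character vector (sample id -> group label)
#' @return the validated vector, classed `SampleGrouping`
#' @export
sample_grouping <- function(x) {
  x <- unlist(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("sample grouping must be a named vector (sample id -> group)")
  dup <- names(x)[duplicated(names(x))]
  if (length(dup))
    stop("sample id(s) mapped more than once: ", paste(unique(dup), collapse = ", "))
  if (anyNA(x) || any(!nzchar(x)))
    stop("every sample must carry a non-empty group label")
  structure(as.character(stats::setNames(x, names(x))),
            names = names(x), class = "SampleGrouping")
}

# group labels of a matrix's samples, in order of first appearance,
# erroring if any matrix sample lacks a group
group_labels_for <- function(m, grouping) {
  sids <- sample_ids(m)
  missing <- setdiff(sids, names(grouping))
  if (length(missing))
    stop("sample(s) without a group: ", paste(missing, collapse = ", "))
  g <- unname(unclass(grouping)[sids])
  list(per_sample = g, levels = unique(g))
}

#' Read an expression matrix from disk
#'
#' Two dialects are supported: a plain TSV (first column = feature ids,
#' header = sample ids) and the value block of a GEO series-matrix file
#' (the lines between `!series_matrix_table_begin` and
#' `!series_matrix_table_end`; all other metadata lines are skipped).
#'
#' @param path file path
#' @param dialect `"tsv"` or `"geo_series_matrix"`
#' @param level declared summarization level of the file, `"gene"` or
#'   `"probe"`
#' @return an [expression_matrix()]
#' @export
read_expression_matrix <- function(path,
                                   dialect = c("tsv", "geo_series_matrix"),
                                   level = c("gene", "probe")) {
  dialect <- match.arg(dialect)
  level <- match.arg(level)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (dialect == "geo_series_matrix") {
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
      stop("no series-matrix value block found in ", path)
    lines <- lines[(beg + 1L):(end - 1L)]
    lines <- gsub('"', "", lines, fixed = TRUE)
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty expression file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L)
    stop("malformed header in ", path, ": need a feature-id column plus >=1 sample")
  samples <- header[-1L]
  dup <- samples[duplicated(samples)]
  if (length(dup))
    stop("duplicate sample id(s) in header of ", path, ": ",
         paste(unique(dup), collapse = ", "))
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  if (!length(body)) stop("expression file has a header but no data rows: ", path)
  nfield <- lengths(body)
  bad <- which(nfield != length(header))
  if (length(bad))
    stop(sprintf("row %d of %s has %d fields, expected %d",
                 bad[[1L]] + 1L, path, nfield[[bad[[1L]]]], length(header)))
  feats <- vapply(body, `[[`, character(1), 1L)
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(samples),
                 dimnames = list(feats, samples))
  for (j in seq_along(samples)) {
    raw <- vapply(body, `[[`, character(1), j + 1L)
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !(raw %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s' of %s",
                   raw[[bad[[1L]]]], feats[[bad[[1L]]]], samples[[j]], path))
    vals[, j] <- num
  }
  if (anyNA(vals))
    stop("missing values in ", path,
         "; expression matrices must be complete (impute or filter first)")
  m <- expression_matrix(vals, level)
  message(sprintf("read %d %s-level features x %d samples from %s",
                  nrow(vals), level, ncol(vals), path))
  m
}

#' Write an expression matrix as TSV
#'
#' Values are written with 17 significant digits so that a read/write
#' round-trip reproduces the matrix to full double precision.
#'
#' @param m an `ExpressionMatrix` (or plain named matrix)
#' @param path output path
#' @export
write_expression_matrix <- function(m, path) {
  m <- as_expression_matrix(m)
  v <- m$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(v)), collapse = "\t"), con)
  rows <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], sprintf("%.17g", v[i, ])), collapse = "\t"),
    character(1))
  writeLines(rows, con)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a line are collapsed with a warning; duplicate
#' set names across lines are an error.
#'
#' @param path GMT file path
#' @return named list of character vectors, classed `GeneSetCollection`,
#'   with a `descriptions` attribute
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("line %d of %s has %d field(s); GMT requires name, description and >=1 gene",
                 short[[1L]], path, lengths(fields)[[short[[1L]]]]))
  nm <- vapply(fields, `[[`, character(1), 1L)
  dup <- nm[duplicated(nm)]
  if (length(dup))
    stop("duplicate gene-set name(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) {
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    genes
  })
  names(sets) <- nm
  ndup <- vapply(sets, function(g) sum(duplicated(g)), integer(1))
  if (any(ndup > 0L)) {
    warning("duplicate genes within set(s) ",
            paste(nm[ndup > 0L], collapse = ", "), "; deduplicated")
    sets <- lapply(sets, unique)
  }
  gene_set_collection(sets, descriptions = stats::setNames(desc, nm))
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene symbols
#' @param descriptions optional named character vector of per-set descriptions
#' @return named list classed `GeneSetCollection`
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set needs a name")
  if (anyDuplicated(names(sets))) stop("gene-set names must be unique")
  if (any(lengths(sets) == 0L)) stop("gene sets must be non-empty")
  structure(lapply(sets, as.character),
            descriptions = descriptions, class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d set(s), sizes %s\n", length(x),
              paste(range(lengths(x)), collapse = "-")))
  invisible(x)
}

#' Write a gene-set collection as GMT
#' @param sets named list of character vectors (or `GeneSetCollection`)
#' @param path output path
#' @param descriptions optional named character vector; defaults to the
#'   collection's `descriptions` attribute, else the set name
#' @export
write_gmt <- function(sets, path, descriptions = attr(sets, "descriptions")) {
  nm <- names(sets)
  if (is.null(descriptions)) descriptions <- stats::setNames(nm, nm)
  lines <- vapply(nm, function(s)
    paste(c(s, unname(descriptions[[s]]), sets[[s]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column sample-to-group TSV
#'
#' Expects a header line `sample_id<TAB>group`.
#' @param path file path
#' @return a [sample_grouping()]
#' @export
read_sample_grouping <- function(path) {
  d <- utils::read.delim(path, header = TRUE, colClasses = "character",
                         check.names = FALSE)
  if (ncol(d) < 2L) stop("sample-group file needs two columns (sample_id, group)")
  sample_grouping(stats::setNames(d[[2L]], d[[1L]]))
}

#' Write a sample-to-group TSV
#' @param grouping a [sample_grouping()]
#' @param path output path
#' @export
write_sample_grouping <- function(grouping, path) {
  utils::write.table(
    data.frame(sample_id = names(grouping), group = unclass(grouping)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene map (two-column TSV)
#'
#' Expects a header line `probe_id<TAB>gene_symbol`; a probe mapped twice is
#' an error (the map must be a function probe -> gene).
#' @param path file path
#' @return named character vector, probe id -> gene symbol
#' @export
read_probe_map <- function(path) {
  d <- utils::read.delim(path, header = TRUE, colClasses = "character",
                         check.names = FALSE)
  if (ncol(d) < 2L) stop("probe map needs two columns (probe_id, gene_symbol)")
  probes <- d[[1L]]
  dup <- probes[duplicated(probes)]
  if (length(dup))
    stop("probe(s) mapped more than once: ", paste(unique(dup), collapse = ", "))
  stats::setNames(d[[2L]], probes)
}

#' Write a probe-to-gene map
#' @param map named character vector (probe id -> gene symbol)
#' @param path output path
#' @export
write_probe_map <- function(map, path) {
  utils::write.table(
    data.frame(probe_id = names(map), gene_symbol = unname(map)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every column onto the same empirical distribution: the i-th
#' largest value of each column is replaced by the mean of the i-th largest
#' values across columns. Ties within a column are resolved in input order,
#' which makes the operation exactly idempotent.
#'
#' @param m an `ExpressionMatrix` or plain named matrix, >= 2 samples,
#'   no missing values
#' @return object of the same kind with identical column distributions
#' @export
quantile_normalize <- function(m) {
  em <- inherits(m, "ExpressionMatrix")
  x <- if (em) m$values else as.matrix(m)
  if (ncol(x) < 2L) stop("quantile normalization needs >= 2 samples")
  if (!all(is.finite(x)))
    stop("missing/non-finite values; impute before quantile normalization")
  sorted <- matrix(apply(x, 2L, sort, method = "radix"), nrow = nrow(x))
  target <- rowMeans(sorted)
  out <- x
  for (j in seq_len(ncol(x)))
    out[order(x[, j], method = "radix"), j] <- target
  if (em) expression_matrix(out, m$level) else out
}

#' Collapse probe sets to genes by maximal standard deviation
#'
#' Keeps, per gene, the single probe set with the largest sample standard
#' deviation (n-1 denominator) across all samples; ties are broken by the
#' lexicographically smaller probe id so the result is independent of input
#' row order. Probes absent from the map are dropped (count reported).
#'
#' @param m probe-level `ExpressionMatrix`
#' @param map named character vector, probe id -> gene symbol
#' @return gene-level `ExpressionMatrix`, rows ordered by gene symbol, with a
#'   `probe_chosen` attribute recording the retained probe per gene
#' @export
collapse_probes_max_sd <- function(m, map) {
  m <- as_expression_matrix(m, level = "probe")
  if (m$level != "probe")
    stop("collapse_probes_max_sd expects a probe-level matrix")
  v <- m$values
  common <- intersect(rownames(v), names(map))
  if (!length(common))
    stop("no probe of the matrix appears in the probe map")
  dropped <- nrow(v) - length(common)
  if (dropped > 0L)
    message(sprintf("dropping %d unmapped probe(s)", dropped))
  genes <- unname(map[common])
  sds <- apply(v[common, , drop = FALSE], 1L, stats::sd)
  ord <- order(genes, -sds, common, method = "radix")
  keep <- ord[!duplicated(genes[ord])]
  probes <- common[keep]
  out <- v[probes, , drop = FALSE]
  rownames(out) <- genes[keep]
  res <- expression_matrix(out, "gene")
  attr(res, "probe_chosen") <- stats::setNames(probes, genes[keep])
  res
}
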