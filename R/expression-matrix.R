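#' Construct a two-condition expression matrix
#'
#' The central data container of the pipeline: a genes x samples matrix of
#' log-scale expression values together with a two-level condition label per
#' sample. Both conditions must have at least two samples, since every
#' downstream stage (differential expression, Pearson correlation) needs
#' within-group replication.
#'
#' @param values numeric matrix, genes in rows, samples in columns; rownames
#'   are gene identifiers, colnames sample identifiers. No missing values.
#' @param condition character (or factor) of length `ncol(values)`, or a named
#'   vector covering all sample identifiers, with exactly two distinct levels.
#' @param scale declared scale of the values (informational; the differential
#'   expression stage assumes log2).
#' @return an object of class `expression_matrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `condition` (factor) and `scale`.
#' @export
expression_matrix <- function(values, condition, scale = "log2") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ID: ",
         rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ID: ",
         colnames(values)[duplicated(colnames(values))][1L])
  if (anyNA(values))
    stop("expression values contain missing entries; apply a missing policy ",
         "at load time (see read_expression)")
  if (!is.null(names(condition))) {
    missing_s <- setdiff(colnames(values), names(condition))
    if (length(missing_s))
      stop("no condition recorded for sample: ", missing_s[1L])
    extra <- setdiff(names(condition), colnames(values))
    if (length(extra))
      stop("unknown sample in condition assignment: ", extra[1L])
    condition <- condition[colnames(values)]
  } else if (length(condition) != ncol(values)) {
    stop("`condition` must cover every sample")
  }
  condition <- factor(as.character(condition))
  if (nlevels(condition) > 2L)
    stop("more than two conditions: ",
         paste(levels(condition), collapse = ", "))
  if (nlevels(condition) < 2L)
    stop("exactly two condition levels required, got ", nlevels(condition))
  if (any(table(condition) < 2L))
    stop("each condition needs at least 2 samples")
  structure(
    list(values = values,
         gene_ids = rownames(values),
         sample_ids = colnames(values),
         condition = stats::setNames(condition, colnames(values)),
         scale = scale),
    class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  tab <- table(x$condition)
  cat(sprintf("expression_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("conditions: %s\n",
              paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix and its condition table from TSV
#'
#' The matrix file is tab-separated with a header: first column gene ID,
#' remaining columns one per sample. The condition file has two columns,
#' sample ID and condition label, covering every sample. Files may be
#' gzip-compressed. Genes containing missing values are handled by
#' `missing_policy`: dropped with a message, or a hard error.
#'
#' @param matrix_path path to the genes x samples TSV.
#' @param condition_path path to the two-column sample/condition TSV.
#' @param missing_policy `"drop_gene"` (default) or `"error"`.
#' @inheritParams expression_matrix
#' @return an [expression_matrix()].
#' @export
read_expression <- function(matrix_path, condition_path,
                            missing_policy = c("drop_gene", "error"),
                            scale = "log2") {
  missing_policy <- match.arg(missing_policy)
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("matrix file needs a gene-ID column plus samples")
  gene_ids <- as.character(raw[[1L]])
  values <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  bad <- rowSums(is.na(values)) > 0L
  if (any(bad)) {
    if (missing_policy == "error")
      stop("missing values in gene: ", gene_ids[bad][1L])
    message(sum(bad), " gene(s) dropped for missing values: ",
            paste(utils::head(gene_ids[bad], 5L), collapse = ", "),
            if (sum(bad) > 5L) ", ..." else "")
    values <- values[!bad, , drop = FALSE]
  }
  cond_tab <- utils::read.delim(condition_path, header = TRUE, sep = "\t",
                                check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(cond_tab) < 2L) stop("condition file needs sample and condition columns")
  condition <- stats::setNames(as.character(cond_tab[[2L]]),
                               as.character(cond_tab[[1L]]))
  expression_matrix(values, condition, scale = scale)
}

#' Write an expression matrix (and its condition table) to TSV
#'
#' Inverse of [read_expression()]: `write_expression` emits the genes x
#' samples matrix with a `gene_id` first column, and optionally the
#' two-column condition table. Full double precision is preserved so that
#' write-then-read is the identity.
#'
#' @param expr an [expression_matrix()].
#' @param matrix_path output path for the matrix TSV.
#' @param condition_path optional output path for the condition TSV.
#' @export
write_expression <- function(expr, matrix_path, condition_path = NULL) {
  df <- data.frame(gene_id = expr$gene_ids,
                   expr$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(df, matrix_path)
  if (!is.null(condition_path)) {
    write_table(data.frame(sample_id = expr$sample_ids,
                           condition = as.character(expr$condition),
                           stringsAsFactors = FALSE),
                condition_path)
  }
  invisible(matrix_path)
}

#' Write a result table as TSV
#'
#' All pipeline tables (DEG tables, cartography tables, enrichment results,
#' survival rankings) are plain data frames written tab-separated with a
#' header, '.' decimal separator, no quoting, rows in stored order. Numeric
#' columns are written at full precision (up to 17 significant digits).
#'
#' @param table a data.frame.
#' @param path output path.
#' @export
write_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (anyDuplicated(names(table))) stop("duplicate column names in table")
  utils::write.table(format(table, digits = 17, scientific = NA,
                            trim = TRUE, justify = "none"),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a result table written by [write_table()]
#'
#' @param path TSV path.
#' @return a data.frame.
#' @export
read_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
}
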