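#' Construct an expression table
#'
#' Per-gene mean expression in the control and treated conditions plus the
#' log2 fold change (treated over control), with an `expressed` flag.
#' Differential-expression estimation is out of scope: the log2 fold
#' change is an input, not something the package computes from counts.
#'
#' @param df data frame with columns `gene_id`, `expr_ctrl`, `expr_trt`,
#'   `log2fc` and optionally `expressed` (default all `TRUE`).
#' @param min_expr optional expression floor: genes with
#'   `expr_ctrl < min_expr` and `expr_trt < min_expr` get `expressed = FALSE`.
#' @return an `ExpressionTable` (data.frame subclass).
#' @export
expression_table <- function(df, min_expr = NULL) {
  req <- c("gene_id", "expr_ctrl", "expr_trt", "log2fc")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop_input("expression table missing columns: %s",
                               paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  df$gene_id <- as.character(df$gene_id)
  if (anyDuplicated(df$gene_id))
    stop_input("duplicate gene_id '%s' in expression table",
               df$gene_id[duplicated(df$gene_id)][1])
  if (is.null(df$expressed)) df$expressed <- TRUE
  if (!is.null(min_expr))
    df$expressed <- df$expressed & (df$expr_ctrl >= min_expr | df$expr_trt >= min_expr)
  if (any(df$expressed & !is.finite(df$log2fc)))
    stop_input("non-finite log2fc for an expressed gene")
  df <- df[c("gene_id", "expr_ctrl", "expr_trt", "log2fc", "expressed")]
  rownames(df) <- NULL
  structure(df, class = c("ExpressionTable", "data.frame"))
}

#' Read an expression table from TSV
#'
#' Expected columns: `gene_id`, `expr_ctrl`, `expr_trt`, `log2fc`,
#' optionally `expressed` (logical or 0/1).
#'
#' @param path TSV file path.
#' @param min_expr see [expression_table()].
#' @return an [expression_table()].
#' @export
read_expression <- function(path, min_expr = NULL) {
  if (!file.exists(path)) stop_input("expression file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(df$expressed)) df$expressed <- as.logical(df$expressed)
  expression_table(df, min_expr = min_expr)
}

#' Write an expression table as TSV
#' @param expr an [expression_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "ExpressionTable"))
  utils::write.table(as.data.frame(expr), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a two-column TSV
#'
#' Column 1 is the set name, column 2 a gene id; one pair per line, with
#' or without a header line `set\tgene_id`.
#'
#' @param path TSV file path.
#' @return named list of character vectors of gene ids.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop_input("gene set file not found: %s", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("set", "gene_id"))
  if (nrow(df) && identical(tolower(df$set[1]), "set")) df <- df[-1, , drop = FALSE]
  lapply(split(df$gene_id, df$set), unique)
}

#' Write gene sets as a two-column TSV
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  df <- data.frame(set = rep(names(sets), lengths(sets)),
                   gene_id = unlist(sets, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
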