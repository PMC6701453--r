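#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids, a first column of gene ids, and
#' numeric cells. Parse problems (ragged rows, duplicate ids, non-numeric
#' cells) are reported with 1-based file line numbers.
#'
#' @param path TSV file path.
#' @return Genes x samples numeric matrix.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (file.size(path) == 0L) {
    stop(sprintf("empty input file: %s", path), call. = FALSE)
  }
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) < 2L) {
    stop(sprintf("no data rows in %s", path), call. = FALSE)
  }
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged row at line %d of %s (%d fields, expected %d)",
                 bad, path, nf[bad], nf[1L]), call. = FALSE)
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    line <- which(duplicated(ids))[1L] + 1L   # +1 for the header line
    stop(sprintf("duplicate gene id '%s' at line %d of %s",
                 ids[duplicated(ids)][1L], line, path), call. = FALSE)
  }
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) &
                         !is.na(vals[[j]]))[1L]
      stop(sprintf("non-numeric value in column '%s' at line %d of %s",
                   names(vals)[j], bad_row + 1L, path), call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' Write an expression matrix as TSV
#'
#' Values are written with 17 significant digits so that
#' `read_expression(write_expression(x))` round-trips exactly.
#'
#' @param expr Genes x samples matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path) {
  expr <- as_expression_matrix(expr)
  chr <- matrix(sprintf("%.17g", expr), nrow = nrow(expr))
  out <- cbind(gene_id = rownames(expr), as.data.frame(chr))
  names(out) <- c("gene_id", colnames(expr))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write any data frame as TSV (tab-separated, no quoting)
#' @param df Data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample/phenotype table from TSV
#'
#' Requires `sample_id` and `group` columns; any further columns are
#' phenotypes (missing values allowed, encoded as `NA`).
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_sample_info <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop(sprintf("%s must contain columns sample_id and group", path),
         call. = FALSE)
  }
  if (!all(df$group %in% c("control", "treated"))) {
    stop("group must be 'control' or 'treated'", call. = FALSE)
  }
  df
}

#' Read a gene annotation table from TSV
#'
#' Requires columns `gene_id`, `symbol`, `is_control`.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  if (!all(c("gene_id", "symbol", "is_control") %in% names(df))) {
    stop(sprintf("%s must contain columns gene_id, symbol, is_control", path),
         call. = FALSE)
  }
  df$is_control <- as.logical(df$is_control)
  df
}

#' Read a two-column 1:1 homolog map from TSV
#'
#' @param path TSV path with columns `gene_a`, `gene_b`.
#' @return Validated data frame.
#' @export
read_homolog_map <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  validate_homolog_map(df)
}
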