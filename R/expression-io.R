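#' Read an expression matrix from TSV
#'
#' Reads a genes-by-conditions expression table: first row condition ids,
#' first column gene ids, numeric non-negative body. Non-numeric cells and
#' duplicated gene ids are errors naming the offending location.
#'
#' @param tsv_text TSV text or a file path.
#' @return Numeric matrix (genes in rows, conditions in columns).
#' @export
read_expression_matrix <- function(tsv_text) {
  path <- .as_file(tsv_text, ".tsv")
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) .stopf("expression table needs gene ids plus >= 1 condition")
  gene_ids <- df[[1L]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0L) .stopf("duplicated gene id '%s'", dup[[1L]])
  body <- df[, -1L, drop = FALSE]
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(body)), nrow = nrow(body))
  )
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    .stopf("non-numeric expression value at gene '%s', condition '%s'",
           gene_ids[[idx[[1L]]]], colnames(body)[[idx[[2L]]]])
  }
  if (any(!is.finite(vals))) .stopf("expression values must be finite")
  if (any(vals < 0)) {
    idx <- which(vals < 0, arr.ind = TRUE)[1L, ]
    .stopf("negative expression value at gene '%s', condition '%s'",
           gene_ids[[idx[[1L]]]], colnames(body)[[idx[[2L]]]])
  }
  dimnames(vals) <- list(gene_ids, colnames(body))
  vals
}

#' Write an expression matrix to TSV
#'
#' @param m Numeric matrix with gene ids as rownames and condition ids as
#'   colnames.
#' @param path Optional output path; text returned when `NULL`.
#' @param id_column Header for the gene-id column.
#' @export
write_expression_matrix <- function(m, path = NULL, id_column = "gene_id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[[1L]] <- id_column
  if (is.null(path)) {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    return(paste0(paste(out, collapse = "\n"), "\n"))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
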