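#' Construct and validate an expression table
#'
#' Transcript-level quantifications (TPM) with a transcript-to-gene map.
#' Validation enforces unique transcript ids, a single gene per transcript,
#' and non-negative TPM values; sample order is preserved as given.
#'
#' @param transcript_id Character vector of transcript ids.
#' @param gene_id Character vector, same length, gene of each transcript.
#' @param tpm Numeric matrix, transcripts x samples, TPM units; column names
#'   are sample ids.
#' @return An object of class `"expression_table"`.
#' @export
expression_table <- function(transcript_id, gene_id, tpm) {
  tpm <- as.matrix(tpm)
  if (anyDuplicated(transcript_id)) stop_format("duplicate transcript ids")
  if (length(transcript_id) != nrow(tpm) || length(gene_id) != nrow(tpm)) {
    stop_format("transcript_id/gene_id length != number of tpm rows")
  }
  if (is.null(colnames(tpm))) stop_format("tpm needs sample column names")
  if (any(!is.finite(tpm)) || any(tpm < 0)) {
    stop_format("TPM values must be finite and non-negative")
  }
  rownames(tpm) <- transcript_id
  structure(list(transcript_id = as.character(transcript_id),
                 gene_id = as.character(gene_id),
                 tpm = tpm,
                 samples = colnames(tpm)),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d transcripts, %d genes, %d samples\n",
              length(x$transcript_id), length(unique(x$gene_id)),
              length(x$samples)))
  invisible(x)
}

#' Read a transcript expression TSV
#'
#' Expected layout: header row, first column transcript id, second column
#' gene id, remaining columns one per sample (TPM).
#'
#' @param path Path to the TSV (plain or gzip).
#' @return An [expression_table()].
#' @export
read_expression <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop_format("expression TSV needs id, gene and >= 1 sample column")
  mat <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(mat)) stop_format("non-numeric TPM values in %s", path)
  expression_table(df[[1]], df[[2]], mat)
}

#' Write a transcript expression TSV
#'
#' @param expr An [expression_table()].
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_table"))
  df <- data.frame(transcript_id = expr$transcript_id,
                   gene_id = expr$gene_id,
                   expr$tpm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample covariate TSV
#'
#' One row per sample; first column (or a column named `sample_id`) holds
#' sample ids. Missing values are rejected.
#'
#' @param path Path to the TSV.
#' @return A data frame with rownames set to sample ids and a `sample_id`
#'   column removed.
#' @export
read_covariates <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  idcol <- if ("sample_id" %in% names(df)) "sample_id" else names(df)[1]
  ids <- as.character(df[[idcol]])
  if (anyDuplicated(ids)) stop_format("duplicate sample ids in covariates")
  df[[idcol]] <- NULL
  if (anyNA(df)) stop_format("covariates contain missing values")
  rownames(df) <- ids
  df
}
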