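## Result tables travel as TSV with a fixed column order and floats at six
## significant digits; streamed writes must be byte-identical to batch
## writes.

.assoc_cols <- c("gene_id", "variant_id", "F", "p_nominal", "md",
                 "p_homoscedasticity", "n_per_group", "flags")
.gene_cols <- c("gene_id", "p_min_observed", "empirical_p", "n_perms",
                "fdr_q", "nominal_threshold", "is_sgene")

.result_schema <- function(df) {
  if (all(.assoc_cols %in% names(df))) return("assoc")
  if (all(.gene_cols %in% names(df))) return("gene")
  stop_format("unrecognised result schema: %s", paste(names(df), collapse = ","))
}

.format_results <- function(df, schema) {
  cols <- if (schema == "assoc") .assoc_cols else .gene_cols
  df <- df[, cols, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  df
}

#' Write association or gene-level results as TSV
#'
#' Accepts a single data frame or a list of data frames (a record stream);
#' all chunks must share the same schema. Column order is fixed
#' (association: gene, variant, F, p_nominal, MD, p_homoscedasticity,
#' n_per_group, flags) and floats are written at 6 significant digits, so
#' streamed and batch writes are identical.
#'
#' @param records Data frame or list of data frames.
#' @param path Output path.
#' @export
write_results <- function(records, path) {
  if (is.data.frame(records)) records <- list(records)
  if (length(records) == 0) stop_format("no records and no schema to write")
  schemas <- vapply(records, .result_schema, character(1))
  if (length(unique(schemas)) > 1) stop_format("mixed result schemas in stream")
  schema <- schemas[1]
  cols <- if (schema == "assoc") .assoc_cols else .gene_cols
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  for (chunk in records) {
    if (nrow(chunk) == 0) next
    write.table(.format_results(chunk, schema), con, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a result TSV written by [write_results()]
#'
#' @param path Path to the TSV.
#' @return A data frame in the fixed column order.
#' @export
read_results <- function(path) {
  read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}
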