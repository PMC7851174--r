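## Filters and transforms turning raw tables into the testable phenotype.
## All filters follow the mapping defaults: gene expressed >= 1 TPM in at
## least 80% of samples (lower-expression samples dropped for that gene),
## >= 2 isoforms with a minimum isoform expression of 0.1 TPM, variants in
## the gene body +/- 5 Kb with MAF >= 0.01 and >= 10 samples per observed
## genotype group.

#' Per-gene splicing ratios with expression filters
#'
#' Computes transcript relative abundances (splicing ratios) for one gene and
#' applies the expression filters: the gene is kept only if its total TPM is
#' at least `min_gene_tpm` in at least `min_prop` of the samples (rounding
#' up); samples below the threshold are dropped for this gene; transcripts
#' below `min_transcript_tpm` in every retained sample are removed. Ratios
#' are computed over the retained transcripts, so each retained row sums to 1
#' exactly.
#'
#' @param expr An [expression_table()].
#' @param gene Gene identifier.
#' @param min_gene_tpm Minimum gene TPM for a sample to be retained (default 1).
#' @param min_prop Minimum proportion of samples passing `min_gene_tpm`
#'   (default 0.8).
#' @param min_transcript_tpm Transcripts never reaching this TPM are removed
#'   (default 0.1).
#' @return An object of class `"splicing_ratios"`: `gene_id`, `ratios`
#'   (samples x transcripts, rows summing to 1), `samples`, `transcripts`,
#'   `dropped_samples` (data frame with reasons), and `status` (`"ok"` or a
#'   skip reason: `"too_few_transcripts"`, `"low_expression"`).
#' @export
compute_ratios <- function(expr, gene, min_gene_tpm = 1, min_prop = 0.8,
                           min_transcript_tpm = 0.1) {
  stopifnot(inherits(expr, "expression_table"))
  idx <- which(expr$gene_id == gene)
  skip <- function(reason) {
    structure(list(gene_id = gene, ratios = NULL, samples = character(0),
                   transcripts = character(0),
                   dropped_samples = data.frame(sample = character(0),
                                                reason = character(0)),
                   status = reason),
              class = "splicing_ratios")
  }
  if (length(idx) < 2) return(skip("too_few_transcripts"))
  tpm <- expr$tpm[idx, , drop = FALSE]
  gene_tpm <- colSums(tpm)
  ok <- gene_tpm >= min_gene_tpm
  if (sum(ok) < ceiling(min_prop * length(ok))) return(skip("low_expression"))
  dropped <- data.frame(sample = colnames(tpm)[!ok],
                        reason = rep("low_gene_expression", sum(!ok)),
                        stringsAsFactors = FALSE)
  tpm <- tpm[, ok, drop = FALSE]
  keep_tx <- apply(tpm, 1L, max) >= min_transcript_tpm
  if (sum(keep_tx) < 2) return(skip("too_few_transcripts"))
  tpm <- tpm[keep_tx, , drop = FALSE]
  denom <- colSums(tpm)
  ratios <- t(tpm) / denom
  structure(list(gene_id = gene,
                 ratios = ratios,
                 samples = rownames(ratios),
                 transcripts = colnames(ratios),
                 dropped_samples = dropped,
                 status = "ok"),
            class = "splicing_ratios")
}

#' Testable cis variants for a gene
#'
#' Restricts a genotype table to the cis window (gene body plus `window` bp
#' on each side) and the gene's retained samples, then applies the
#' testability rules on those samples: biallelic (guaranteed on read),
#' minor allele frequency at least `min_maf`, and every observed dosage
#' group with at least `min_group` samples. Missing dosages (-1) are
#' ignored when computing MAF and group sizes; they are dropped per variant
#' at test time.
#'
#' @param geno A [genotype_table()].
#' @param gene A list or one-row data frame with `chrom`, `start`, `end`
#'   (0-based half-open gene body).
#' @param retained_samples Character vector of samples retained for the gene.
#' @param window Cis window half-width in bp (default 5000).
#' @param min_maf Minimum minor allele frequency (default 0.01).
#' @param min_group Minimum samples per observed genotype group (default 10).
#' @return An object of class `"testable_variants"`: `gene_id` (if supplied),
#'   `variant_id`, `dosages` (variants x retained samples), `cis_window`.
#' @export
filter_variants <- function(geno, gene, retained_samples, window = 5000L,
                            min_maf = 0.01, min_group = 10L) {
  stopifnot(inherits(geno, "genotype_table"))
  missing_s <- setdiff(retained_samples, geno$samples)
  if (length(missing_s)) {
    stop_format("samples absent from genotypes: %s",
                paste(head(missing_s, 3), collapse = ", "))
  }
  win <- c(max(0L, gene$start - window), gene$end + window)
  in_cis <- geno$variants$chrom == gene$chrom &
    geno$variants$start >= win[1] & geno$variants$start < win[2]
  dos <- geno$dosages[in_cis, retained_samples, drop = FALSE]
  keep <- apply(dos, 1L, function(d) {
    d <- d[d >= 0]
    if (length(d) == 0) return(FALSE)
    af <- mean(d) / 2
    maf <- min(af, 1 - af)
    if (maf < min_maf) return(FALSE)
    cnt <- table(d)
    all(cnt >= min_group)
  })
  structure(list(gene_id = gene$gene_id %||% NA_character_,
                 variant_id = geno$variants$variant_id[in_cis][keep],
                 dosages = dos[keep, , drop = FALSE],
                 cis_window = win),
            class = "testable_variants")
}

#' Covariate adjustment of splicing ratios
#'
#' Square-root transforms the splicing ratios (so that Euclidean geometry on
#' the adjusted matrix corresponds to Hellinger geometry on the ratios) and
#' regresses each transcript coordinate on the covariates with an intercept,
#' returning the residual matrix. Categorical covariates are expanded to
#' indicators with the reference level dropped. With no covariates the
#' result is the centered square-root ratios. Collinear covariate columns
#' are dropped with a warning.
#'
#' @param ratios A `"splicing_ratios"` object with `status == "ok"`.
#' @param covariates A data frame with a `sample_id` column (or rownames)
#'   and covariate columns, or `NULL`.
#' @return An object of class `"adjusted_phenotype"`: `gene_id`, `matrix`
#'   (samples x transcripts sqrt-scale residuals), `center` (per-transcript
#'   grand mean of sqrt ratios, used to reconstruct adjusted relative
#'   expression), `samples`, `transcripts`.
#' @export
adjust_covariates <- function(ratios, covariates = NULL) {
  stopifnot(inherits(ratios, "splicing_ratios"))
  if (!identical(ratios$status, "ok")) {
    stop_format("gene %s was skipped (%s)", ratios$gene_id, ratios$status)
  }
  Y <- sqrt(ratios$ratios)
  center <- colMeans(Y)
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    res <- sweep(Y, 2L, center)
  } else {
    cov <- as.data.frame(covariates)
    if ("sample_id" %in% names(cov)) {
      rownames(cov) <- cov$sample_id
      cov$sample_id <- NULL
    }
    missing_s <- setdiff(ratios$samples, rownames(cov))
    if (length(missing_s)) {
      stop_format("covariates missing for samples: %s",
                  paste(head(missing_s, 3), collapse = ", "))
    }
    cov <- cov[ratios$samples, , drop = FALSE]
    if (anyNA(cov)) stop_format("covariates contain missing values")
    X <- model.matrix(~ ., data = cov)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      warning(sprintf("dropping %d collinear covariate column(s)",
                      ncol(X) - qx$rank))
    }
    res <- qr.resid(qx, Y)
  }
  structure(list(gene_id = ratios$gene_id,
                 matrix = res,
                 center = center,
                 samples = ratios$samples,
                 transcripts = ratios$transcripts),
            class = "adjusted_phenotype")
}
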