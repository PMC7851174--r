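#' Map cis sQTLs in one cohort
#'
#' The main fitting function. For every gene with at least two expressed
#' isoforms it computes splicing ratios, applies the expression filters,
#' adjusts covariates on the square-root scale, selects the testable cis
#' variants (gene body +/- `window` bp, MAF and group-size rules), and tests
#' each variant-gene pair with the Hellinger-distance pseudo-F: nominal
#' p-value in the requested permutation mode, MD effect size, and the
#' multivariate homoscedasticity screen. The adjusted phenotype and distance
#' geometry are computed once per gene and reused across variants. After the
#' scan, homoscedasticity p-values are corrected (BH across all nominal
#' tests) and failing pairs are flagged `heteroscedastic`; they stay in the
#' result (and in later multiple-testing correction) but are never reported
#' as significant.
#'
#' Samples with missing dosage are dropped from that variant's test only,
#' and the MAF/group-size rules are re-checked on the remaining samples.
#'
#' @param expr An [expression_table()].
#' @param geno A [genotype_table()].
#' @param genes A `"gene_annotation"` object (see [read_gene_annotation()]
#'   or [simulate_gene_annotation()]).
#' @param covariates Covariate data frame (or `NULL`).
#' @inheritParams nominal_pvalue
#' @param window Cis window half-width in bp.
#' @param min_maf,min_group Variant testability rules.
#' @param homoscedasticity_B Label permutations for the dispersion screen.
#' @param seed Integer seed driving all permutation streams.
#' @return An object of class `"sqtl_scan"`: `results` (one row per tested
#'   variant-gene pair), `skipped` (genes with reasons), `gene_data`
#'   (per-gene phenotype and dosages, reused by [sqtl_permute()]), `params`.
#' @seealso [sqtl_permute()], [significant_pairs()]
#' @export
sqtl_seek <- function(expr, geno, genes, covariates = NULL,
                      mode = c("approx", "mc_perm", "exact_perm"),
                      B = 1000L, B0 = 500L, window = 5000L,
                      min_maf = 0.01, min_group = 10L,
                      homoscedasticity_B = 999L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(expr, "expression_table"), inherits(geno, "genotype_table"))
  gene_df <- genes$genes
  rows <- list()
  skipped <- list()
  gene_data <- list()
  for (gi in seq_len(nrow(gene_df))) {
    grow <- gene_df[gi, ]
    gid <- grow$gene_id
    if (!gid %in% expr$gene_id) next
    rat <- compute_ratios(expr, gid)
    if (!identical(rat$status, "ok")) {
      skipped[[gid]] <- rat$status
      next
    }
    ph <- adjust_covariates(rat, covariates)
    tv <- filter_variants(geno, grow, ph$samples, window = window,
                          min_maf = min_maf, min_group = min_group)
    if (length(tv$variant_id) == 0) {
      skipped[[gid]] <- "no_testable_variants"
      next
    }
    tails <- list()
    for (vi in seq_along(tv$variant_id)) {
      vid <- tv$variant_id[vi]
      dos <- tv$dosages[vi, ]
      use <- dos >= 0
      d <- dos[use]
      ## re-check testability after missing-dosage removal
      af <- mean(d) / 2
      if (min(af, 1 - af) < min_maf || any(table(d) < min_group)) next
      Y <- ph$matrix[use, , drop = FALSE]
      g <- factor(d)
      vseed <- child_seed(seed, paste0(gid, ":", vid))
      np <- nominal_pvalue(Y, g, mode = mode, B = B, B0 = B0, seed = vseed)
      if (!np$degenerate) {
        gm <- group_adjusted_means(ph$matrix[use, , drop = FALSE], ph$center, g)
        md <- effect_size_md(gm)
        hom <- homoscedasticity_test(Y, g, B = homoscedasticity_B,
                                     seed = vseed + 1L)
      } else {
        md <- NA_real_
        hom <- list(p = NA_real_)
      }
      if (!is.null(np$tail)) tails[[vid]] <- np$tail
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, variant_id = vid,
        F = np$F, p_nominal = np$p, md = md,
        p_homoscedasticity = hom$p,
        n_per_group = paste(table(g), collapse = "/"),
        n_perms_used = np$n_perms_used,
        flags = if (np$degenerate) "degenerate" else "",
        stringsAsFactors = FALSE)
    }
    gene_data[[gid]] <- list(Y = ph$matrix, center = ph$center,
                             samples = ph$samples,
                             dosages = tv$dosages, variant_id = tv$variant_id,
                             tails = tails)
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), variant_id = character(0),
               F = numeric(0), p_nominal = numeric(0), md = numeric(0),
               p_homoscedasticity = numeric(0), n_per_group = character(0),
               n_perms_used = integer(0), flags = character(0),
               stringsAsFactors = FALSE)
  ## dispersion screen: FDR across all nominal homoscedasticity tests
  ok <- !is.na(results$p_homoscedasticity)
  if (any(ok)) {
    qh <- rep(NA_real_, nrow(results))
    qh[ok] <- p.adjust(results$p_homoscedasticity[ok], method = "BH")
    het <- ok & qh < 0.05
    results$flags[het] <- sub("^;", "", paste(results$flags[het],
                                              "heteroscedastic", sep = ";"))
    results$flags <- sub("^;", "", results$flags)
  }
  structure(list(results = results,
                 skipped = data.frame(gene_id = names(skipped),
                                      reason = unlist(skipped) %||% character(0),
                                      stringsAsFactors = FALSE),
                 gene_data = gene_data,
                 params = list(mode = mode, B = B, B0 = B0, window = window,
                               min_maf = min_maf, min_group = min_group,
                               homoscedasticity_B = homoscedasticity_B,
                               seed = seed),
                 call = match.call()),
            class = "sqtl_scan")
}

#' @export
print.sqtl_scan <- function(x, ...) {
  cat("sQTL scan (Hellinger-distance pseudo-F)\n")
  cat(sprintf("  %d variant-gene tests across %d genes (%d skipped)\n",
              nrow(x$results), length(x$gene_data), nrow(x$skipped)))
  cat(sprintf("  mode = %s, seed = %d\n", x$params$mode, x$params$seed))
  invisible(x)
}

#' @export
summary.sqtl_scan <- function(object, ...) {
  r <- object$results
  out <- list(n_tests = nrow(r),
              n_genes = length(unique(r$gene_id)),
              n_skipped = nrow(object$skipped),
              p_quantiles = quantile(r$p_nominal, c(0, .25, .5, .75, 1),
                                     na.rm = TRUE),
              md_quantiles = quantile(r$md, c(0, .25, .5, .75, 1), na.rm = TRUE),
              n_heteroscedastic = sum(grepl("heteroscedastic", r$flags)))
  class(out) <- "summary.sqtl_scan"
  out
}

#' @export
print.summary.sqtl_scan <- function(x, ...) {
  cat(sprintf("sQTL scan summary: %d tests, %d genes (%d skipped), %d heteroscedastic\n",
              x$n_tests, x$n_genes, x$n_skipped, x$n_heteroscedastic))
  cat("  nominal p quantiles:\n")
  print(signif(x$p_quantiles, 3))
  cat("  MD quantiles:\n")
  print(signif(x$md_quantiles, 3))
  invisible(x)
}

#' Histogram of nominal p-values from a scan
#'
#' @param x An `"sqtl_scan"` object.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.sqtl_scan <- function(x, ...) {
  hist(x$results$p_nominal, breaks = 20, main = "Nominal p-values",
       xlab = "p", ...)
  abline(h = nrow(x$results) / 20, lty = 2)
  invisible(x)
}
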