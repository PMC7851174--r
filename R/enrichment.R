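## Matched-null functional enrichment, positional profiles, heteropleiotropy
## calling and splice-site PWM delta scoring.

#' Matched-null sampling specification
#'
#' @param n_sets Number of null variant sets (default 1000).
#' @param n_bins Gene-relative location bins (default 20).
#' @param maf_tol MAF matching tolerance (default 0.02).
#' @param top_k_per_gene sQTLs retained per gene for enrichment (default 10).
#' @param min_mean_freq Tracks with a smaller mean annotated count across
#'   null sets are dropped (default 5).
#' @return An object of class `"matched_null_spec"`.
#' @export
matched_null_spec <- function(n_sets = 1000L, n_bins = 20L, maf_tol = 0.02,
                              top_k_per_gene = 10L, min_mean_freq = 5) {
  if (maf_tol <= 0 || maf_tol >= 0.5) stop_format("maf_tol must lie in (0, 0.5)")
  if (any(c(n_sets, n_bins, top_k_per_gene, min_mean_freq) <= 0)) {
    stop_format("all matched-null parameters must be positive")
  }
  structure(list(n_sets = as.integer(n_sets), n_bins = as.integer(n_bins),
                 maf_tol = maf_tol, top_k_per_gene = as.integer(top_k_per_gene),
                 min_mean_freq = min_mean_freq),
            class = "matched_null_spec")
}

#' Sample location- and MAF-matched null variant sets
#'
#' Draws `n_sets` sets of non-sQTL variants, each the size of the sQTL set,
#' matching every sQTL slot on gene-relative location bin (same `n_bins`
#' scheme as [location_profile()]) and MAF within `maf_tol`. Sampling is
#' without replacement within a set and with replacement across sets. An
#' empty matched stratum falls back to the nearest-MAF in-bin candidate
#' (logged via attribute `n_fallback`); a whole bin without candidates is
#' an error.
#'
#' @param sqtls Data frame with columns `variant_id`, `maf`, `bin`.
#' @param candidates Data frame of non-sQTL candidates with the same
#'   columns.
#' @param spec A [matched_null_spec()].
#' @param seed Integer seed.
#' @return List of `n_sets` character vectors of candidate variant ids,
#'   with attribute `n_fallback`.
#' @export
sample_matched_null <- function(sqtls, candidates, spec = matched_null_spec(),
                                seed = NULL) {
  stopifnot(inherits(spec, "matched_null_spec"))
  n <- nrow(sqtls)
  ## precompute per-slot candidate index pools
  pools <- vector("list", n)
  fallback <- 0L
  for (i in seq_len(n)) {
    in_bin <- which(candidates$bin == sqtls$bin[i])
    if (length(in_bin) == 0) {
      stop_format("no candidates in location bin %s", sqtls$bin[i])
    }
    ok <- in_bin[abs(candidates$maf[in_bin] - sqtls$maf[i]) <= spec$maf_tol]
    if (length(ok) == 0) {
      fallback <- fallback + 1L
      ok <- in_bin[which.min(abs(candidates$maf[in_bin] - sqtls$maf[i]))]
    }
    pools[[i]] <- ok
  }
  sets <- with_seed(seed, {
    lapply(seq_len(spec$n_sets), function(s) {
      taken <- integer(0)
      out <- integer(n)
      for (i in seq_len(n)) {
        avail <- setdiff(pools[[i]], taken)
        if (length(avail) == 0) avail <- pools[[i]]  # pool exhausted in-set
        pick <- if (length(avail) == 1) avail else sample(avail, 1L)
        out[i] <- pick
        taken <- c(taken, pick)
      }
      candidates$variant_id[out]
    })
  })
  attr(sets, "n_fallback") <- fallback
  sets
}

#' Odds-ratio enrichment of sQTLs over matched null sets
#'
#' For each annotation track, forms the 2x2 table of annotated vs
#' not-annotated counts for the sQTL set against the mean annotated count
#' across the null sets (rounded half-up), and reports the odds ratio with
#' a two-sided Fisher exact p-value. Tracks whose mean annotated count
#' across null sets is below `spec$min_mean_freq` are dropped; BH FDR is
#' computed over the remaining tracks. Zero cells get a Haldane 0.5
#' correction for the OR only (the Fisher test uses the raw counts).
#'
#' @param sqtl_annot Named list: per track, logical vector over the sQTL
#'   set (annotated or not).
#' @param null_annot Named list: per track, numeric vector of annotated
#'   counts in each null set.
#' @param n_null_size Size of each null set (defaults to the sQTL set size).
#' @param spec A [matched_null_spec()].
#' @return Data frame: `annotation`, `n_sqtl_annotated`,
#'   `mean_null_annotated`, `or_value`, `fisher_p`, `fdr_q`.
#' @export
enrichment_or <- function(sqtl_annot, null_annot, n_null_size = NULL,
                          spec = matched_null_spec()) {
  tracks <- names(sqtl_annot)
  rows <- lapply(tracks, function(tr) {
    x <- sqtl_annot[[tr]]
    n1 <- length(x)
    a <- sum(x)
    mean_null <- mean(null_annot[[tr]])
    n0 <- n_null_size %||% n1
    c_ <- round_half_up(mean_null)
    tab <- matrix(c(a, n1 - a, c_, n0 - c_), nrow = 2)
    or <- if (any(tab == 0)) {
      ((a + 0.5) * (n0 - c_ + 0.5)) / ((n1 - a + 0.5) * (c_ + 0.5))
    } else {
      (a * (n0 - c_)) / ((n1 - a) * c_)
    }
    data.frame(annotation = tr, n_sqtl_annotated = a,
               mean_null_annotated = mean_null,
               or_value = or,
               ## fisher.test can exceed 1 by floating error when summing
               ## tail densities; clamp to the valid range
               fisher_p = min(fisher.test(tab)$p.value, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$mean_null_annotated >= spec$min_mean_freq, , drop = FALSE]
  if (nrow(out)) out$fdr_q <- bh_fdr(out$fisher_p)
  rownames(out) <- NULL
  out
}

#' Assign positions to gene-relative location bins
#'
#' @param pos 0-based positions.
#' @param start,end Region bounds (0-based half-open).
#' @param strand `"+"` or `"-"`; bin 1 is the 5' end.
#' @param n_bins Number of bins.
#' @return Integer bin indices (NA outside the region).
#' @export
location_bin <- function(pos, start, end, strand = "+", n_bins = 20L) {
  rel <- (pos - start) / (end - start)
  bin <- floor(rel * n_bins) + 1L
  bin[pos < start | pos >= end] <- NA_integer_
  bin[bin > n_bins] <- n_bins
  if (strand == "-") bin <- n_bins + 1L - bin
  as.integer(bin)
}

#' Mean per-bin location profile of sQTLs
#'
#' Divides each region (gene body, exon, intron or flank) into `n_bins`
#' equal bins oriented 5' to 3', assigns each sQTL to its bin, computes
#' per-gene bin proportions (over the gene's own sQTL count) and averages
#' them across genes. The 20% shortest regions are removed first to ensure
#' a minimum bin size. Under no positional preference the mean profile is
#' flat at `1/n_bins`.
#'
#' @param sqtls Data frame with `gene_id` and `pos` (0-based).
#' @param regions Data frame with `gene_id`, `start`, `end`, `strand`.
#' @param n_bins Number of bins (default 20).
#' @param min_length_quantile Fraction of shortest regions removed
#'   (default 0.2).
#' @return Numeric vector of mean per-bin proportions (sums to 1), with
#'   attribute `n_excluded` (sQTLs outside their region).
#' @export
location_profile <- function(sqtls, regions, n_bins = 20L,
                             min_length_quantile = 0.2) {
  len <- regions$end - regions$start
  keep <- len >= quantile(len, min_length_quantile)
  regions <- regions[keep, , drop = FALSE]
  excluded <- 0L
  per_gene <- list()
  for (i in seq_len(nrow(regions))) {
    g <- regions$gene_id[i]
    sq <- sqtls[sqtls$gene_id == g, , drop = FALSE]
    if (nrow(sq) == 0) next
    bins <- location_bin(sq$pos, regions$start[i], regions$end[i],
                         regions$strand[i], n_bins)
    excluded <- excluded + sum(is.na(bins))
    bins <- bins[!is.na(bins)]
    if (length(bins) == 0) next
    per_gene[[g]] <- tabulate(bins, nbins = n_bins) / length(bins)
  }
  if (length(per_gene) == 0) stop_format("no sQTLs fall inside the regions")
  out <- colMeans(do.call(rbind, per_gene))
  attr(out, "n_excluded") <- excluded
  out
}

#' Heteropleiotropy call for a variant
#'
#' A variant `v` is heteropleiotropic across genes (g1, g2) and tissues
#' (t1, t2) when (i) it is an sQTL but not an eQTL for g1 in t1, (ii) an
#' eQTL but not an sQTL for g2 in t2, (iii) neither for g2 in t1, and (iv)
#' neither for g1 in t2. Any missing call makes the variant not evaluable
#' (`NA`, distinct from `FALSE`).
#'
#' @param calls Named logical vector (or list) with elements
#'   `sqtl_g1_t1`, `eqtl_g1_t1`, `sqtl_g2_t1`, `eqtl_g2_t1`,
#'   `sqtl_g1_t2`, `eqtl_g1_t2`, `sqtl_g2_t2`, `eqtl_g2_t2`.
#' @return `TRUE`, `FALSE`, or `NA` when not evaluable.
#' @export
heteropleiotropy_call <- function(calls) {
  need <- c("sqtl_g1_t1", "eqtl_g1_t1", "sqtl_g2_t1", "eqtl_g2_t1",
            "sqtl_g1_t2", "eqtl_g1_t2", "sqtl_g2_t2", "eqtl_g2_t2")
  cl <- unlist(calls)[need]
  if (anyNA(cl)) return(NA)
  (cl["sqtl_g1_t1"] && !cl["eqtl_g1_t1"]) &&
    (cl["eqtl_g2_t2"] && !cl["sqtl_g2_t2"]) &&
    (!cl["sqtl_g2_t1"] && !cl["eqtl_g2_t1"]) &&
    (!cl["sqtl_g1_t2"] && !cl["eqtl_g1_t2"])
}

#' PWM delta score of a variant in a splice site
#'
#' Scores a splice-site sequence under a position weight matrix as
#' \eqn{\sum_i \log_2(p_i(base_i) / 0.25)} for the reference and the
#' alternative allele, and returns the absolute score difference — the
#' estimated change in splice-site strength.
#'
#' @param site_seq Character site sequence (A/C/G/T).
#' @param variant List with `offset` (1-based position of the substitution
#'   within the site), `ref`, `alt` (single bases).
#' @param pwm 4-row matrix (rownames A, C, G, T), one column per site
#'   position, columns summing to 1 (apply a pseudocount upstream).
#' @return List with `score_ref`, `score_alt`, `delta`.
#' @export
pwm_delta <- function(site_seq, variant, pwm) {
  bases <- strsplit(toupper(site_seq), "")[[1]]
  if (ncol(pwm) != length(bases)) {
    stop_format("PWM has %d columns but site has %d bases", ncol(pwm), length(bases))
  }
  off <- variant$offset
  if (is.null(off) || off < 1 || off > length(bases)) {
    stop_format("variant lies outside the site")
  }
  if (nchar(variant$ref) != 1 || nchar(variant$alt) != 1) {
    stop_format("indels are not supported for PWM scoring")
  }
  if (bases[off] != toupper(variant$ref)) {
    stop_format("reference base mismatch at offset %d (%s vs %s)",
                off, bases[off], variant$ref)
  }
  score <- function(b) {
    sum(log2(pwm[cbind(match(b, rownames(pwm)), seq_along(b))] / 0.25))
  }
  s_ref <- score(bases)
  bases[off] <- toupper(variant$alt)
  s_alt <- score(bases)
  list(score_ref = s_ref, score_alt = s_alt, delta = abs(s_alt - s_ref))
}
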