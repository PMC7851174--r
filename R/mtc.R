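## Gene-level significance: adaptive phenotype permutations characterise,
## for each gene, the null distribution of the minimum nominal p-value
## across its cis variants; BH over the resulting empirical p-values calls
## sGenes; a genome-wide empirical threshold maps back to per-gene nominal
## thresholds to retrieve every significant variant-gene pair.

## method-of-moments Beta fit; NULL when degenerate
.beta_fit <- function(x) {
  m <- mean(x)
  v <- var(x)
  if (!is.finite(v) || v <= 0 || m <= 0 || m >= 1) return(NULL)
  k <- m * (1 - m) / v - 1
  if (k <= 0) return(NULL)
  list(shape1 = m * k, shape2 = (1 - m) * k)
}

#' Gene-level empirical p-value by adaptive permutations
#'
#' Permutes the phenotype rows jointly (preserving LD among the gene's
#' variants), records the minimum nominal p-value across variants for each
#' permutation, and stops adaptively once `hit_target` permutation minima
#' fall at or below the observed minimum (after at least `B_min`
#' permutations) or `B_max` is reached. The empirical p-value is
#' `(1 + hits) / (1 + B)`. Per-variant nominal p-values under permutation
#' reuse the variant's moment-matched permutation tail fit: label
#' permutation leaves that null distribution invariant, so the fit is
#' computed once per variant.
#'
#' @param Y Adjusted phenotype matrix (samples x transcripts).
#' @param dosages Variants-by-samples dosage matrix (missing = -1).
#' @param observed_min Observed minimum nominal p across the variants.
#' @param tails Optional named list of per-variant tail fits (from a scan in
#'   `approx` mode); missing fits are computed with `B0` permutations.
#' @param B_min,B_max,hit_target Adaptive scheme constants.
#' @param B0 Permutation batch for missing tail fits.
#' @param seed Integer seed.
#' @return A list: `empirical_p`, `n_perms`, `hits`, `minima` (the
#'   permutation minima), `beta` (Beta tail fit of the minima or `NULL`).
#' @export
gene_empirical_p <- function(Y, dosages, observed_min, tails = NULL,
                             B_min = 100L, B_max = 1000L, hit_target = 10L,
                             B0 = 500L, seed = NULL) {
  Y <- as.matrix(Y)
  dosages <- matrix(as.integer(dosages), nrow = NROW(dosages))
  n <- nrow(Y)
  nv <- nrow(dosages)
  if (nv == 0) stop_format("no testable variants")
  vinfo <- vector("list", nv)
  with_seed(seed, {
    for (v in seq_len(nv)) {
      use <- dosages[v, ] >= 0
      g <- factor(dosages[v, use])
      fit <- tails[[v]] %||% NULL
      if (is.null(fit)) {
        fs <- .perm_fs_Y(Y[use, , drop = FALSE], g, B0)
        fit <- .tail_fit(fs)
      }
      vinfo[[v]] <- list(use = use, g = g, ng = tabulate(g),
                         k = nlevels(g), fit = fit)
    }
    minima <- numeric(B_max)
    hits <- 0L
    b <- 0L
    while (b < B_max) {
      b <- b + 1L
      perm <- sample.int(n)
      pm <- 1
      for (v in seq_len(nv)) {
        vi <- vinfo[[v]]
        Yp <- Y[perm, , drop = FALSE][vi$use, , drop = FALSE]
        ss <- .ss_Y(Yp, vi$g)
        f <- .f_from_ss(ss$ssb, ss$sst, vi$k, sum(vi$ng))
        pv <- .tail_p(f, vi$fit)
        if (pv < pm) pm <- pv
      }
      minima[b] <- pm
      if (pm <= observed_min) hits <- hits + 1L
      if (hits >= hit_target && b >= B_min) break
    }
    minima <- minima[seq_len(b)]
    list(empirical_p = (1 + hits) / (1 + b), n_perms = b, hits = hits,
         minima = minima, beta = .beta_fit(minima))
  })
}

#' Adaptive gene-level permutation pass over a scan
#'
#' Runs [gene_empirical_p()] for every gene in an [sqtl_seek()] result,
#' reusing the per-variant permutation tail fits stored by the scan.
#'
#' @param scan An `"sqtl_scan"` object.
#' @param B_min,B_max,hit_target Adaptive scheme constants (defaults 100,
#'   1000, 10).
#' @param seed Integer seed (defaults to the scan's seed + 1).
#' @return An object of class `"sqtl_perm"`: `genes` (data frame with
#'   `gene_id`, `p_min_observed`, `empirical_p`, `n_perms`, `beta_shape1`,
#'   `beta_shape2`) and `minima` (per-gene permutation minima).
#' @export
sqtl_permute <- function(scan, B_min = 100L, B_max = 1000L, hit_target = 10L,
                         seed = NULL) {
  stopifnot(inherits(scan, "sqtl_scan"))
  seed <- seed %||% (scan$params$seed + 1L)
  gids <- intersect(names(scan$gene_data), unique(scan$results$gene_id))
  rows <- vector("list", length(gids))
  minima <- vector("list", length(gids))
  for (i in seq_along(gids)) {
    gid <- gids[i]
    gd <- scan$gene_data[[gid]]
    res <- scan$results[scan$results$gene_id == gid &
                          scan$results$flags != "degenerate", , drop = FALSE]
    if (nrow(res) == 0) next
    tested <- match(res$variant_id, gd$variant_id)
    obs_min <- min(res$p_nominal)
    ep <- gene_empirical_p(gd$Y, gd$dosages[tested, , drop = FALSE],
                           observed_min = obs_min,
                           tails = gd$tails[res$variant_id],
                           B_min = B_min, B_max = B_max,
                           hit_target = hit_target, B0 = scan$params$B0,
                           seed = child_seed(seed, gid))
    rows[[i]] <- data.frame(gene_id = gid, p_min_observed = obs_min,
                            empirical_p = ep$empirical_p,
                            n_perms = ep$n_perms,
                            beta_shape1 = ep$beta$shape1 %||% NA_real_,
                            beta_shape2 = ep$beta$shape2 %||% NA_real_,
                            stringsAsFactors = FALSE)
    minima[[i]] <- ep$minima
  }
  names(minima) <- gids
  structure(list(genes = do.call(rbind, rows), minima = minima,
                 params = list(B_min = B_min, B_max = B_max,
                               hit_target = hit_target, seed = seed)),
            class = "sqtl_perm")
}

#' @export
print.sqtl_perm <- function(x, ...) {
  cat(sprintf("gene-level permutation pass: %d genes, %d-%d perms (adaptive)\n",
              nrow(x$genes), x$params$B_min, x$params$B_max))
  invisible(x)
}

#' Benjamini-Hochberg FDR q-values
#'
#' Validating wrapper around the step-up procedure: q-values are monotone
#' non-decreasing in p-value rank.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Vector of q-values.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) stop_format("empty p-value vector")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop_format("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Retrieve all significant variant-gene pairs
#'
#' Calls sGenes by BH FDR on the gene-level empirical p-values, then maps a
#' genome-wide empirical threshold back to per-gene nominal thresholds: the
#' threshold `p_t` is the midpoint between the largest empirical p-value
#' passing BH at `fdr` and the smallest failing one; for each sGene the
#' nominal threshold is the `p_t` quantile of that gene's permutation-minima
#' distribution (Beta fit when available, else the empirical quantile). A
#' variant-gene pair is reported significant when its nominal p-value is at
#' or below the gene's threshold, its MD is at least `md_min`, and it passes
#' the homoscedasticity screen.
#'
#' @param scan An `"sqtl_scan"` object.
#' @param perm The matching `"sqtl_perm"` object.
#' @param fdr Gene-level FDR threshold (default 0.05).
#' @param md_min Minimum reported effect size (default 0.05).
#' @return An object of class `"sqtl_significance"`: `genes` (gene-level
#'   table with `fdr_q`, `nominal_threshold`, `is_sgene`), `pairs`
#'   (significant variant-gene pairs), `p_t`.
#' @export
significant_pairs <- function(scan, perm, fdr = 0.05, md_min = 0.05) {
  stopifnot(inherits(scan, "sqtl_scan"), inherits(perm, "sqtl_perm"))
  genes <- perm$genes
  genes$fdr_q <- bh_fdr(genes$empirical_p)
  genes$is_sgene <- genes$fdr_q <= fdr
  if (!any(genes$is_sgene)) {
    genes$nominal_threshold <- NA_real_
    return(structure(list(genes = genes,
                          pairs = scan$results[0, ], p_t = NA_real_),
                     class = "sqtl_significance"))
  }
  pass <- max(genes$empirical_p[genes$is_sgene])
  fail <- if (any(!genes$is_sgene)) min(genes$empirical_p[!genes$is_sgene]) else 1
  p_t <- (pass + fail) / 2
  genes$nominal_threshold <- NA_real_
  pair_rows <- list()
  for (i in which(genes$is_sgene)) {
    gid <- genes$gene_id[i]
    thr <- if (is.finite(genes$beta_shape1[i])) {
      qbeta(p_t, genes$beta_shape1[i], genes$beta_shape2[i])
    } else {
      quantile(perm$minima[[gid]], p_t, type = 1, names = FALSE)
    }
    genes$nominal_threshold[i] <- thr
    r <- scan$results
    sel <- r$gene_id == gid & r$p_nominal <= thr &
      !is.na(r$md) & r$md >= md_min &
      !grepl("heteroscedastic|degenerate", r$flags)
    if (any(sel)) pair_rows[[gid]] <- r[sel, , drop = FALSE]
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else scan$results[0, ]
  rownames(pairs) <- NULL
  structure(list(genes = genes, pairs = pairs, p_t = p_t),
            class = "sqtl_significance")
}

#' @export
print.sqtl_significance <- function(x, ...) {
  cat(sprintf("sQTL significance: %d sGenes of %d, %d significant pairs (p_t = %.4g)\n",
              sum(x$genes$is_sgene), nrow(x$genes), nrow(x$pairs), x$p_t))
  invisible(x)
}

#' Proportion of true positives among replication p-values (pi1)
#'
#' Estimates \eqn{\pi_1 = 1 - \pi_0} with the lambda-grid method:
#' \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} / (n (1 - \lambda))} over a
#' grid, smoothed with a cubic spline and evaluated at the largest lambda.
#' For fewer than 100 p-values a bootstrap selection of the best single
#' lambda (minimum estimated MSE) replaces the smoother. The estimate is
#' clamped to \eqn{[0, 1]}.
#'
#' @param p Replication p-values in (0, 1].
#' @param lambda Grid of lambda values (default 0.05 to 0.95 by 0.05).
#' @return The estimated pi1.
#' @export
pi1 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (length(p) == 0) stop_format("empty p-value vector")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop_format("p-values must lie in (0, 1]")
  }
  n <- length(p)
  pi0_l <- vapply(lambda, function(l) sum(p > l) / (n * (1 - l)), numeric(1))
  pi0 <- if (n >= 100) {
    fit <- smooth.spline(lambda, pi0_l, df = 3)
    predict(fit, x = max(lambda))$y
  } else {
    ## bootstrap lambda selection for small n
    min_pi0 <- max(min(pi0_l), 0)
    mse <- vapply(seq_along(lambda), function(i) {
      boots <- vapply(seq_len(100), function(b) {
        pb <- sample(p, n, replace = TRUE)
        sum(pb > lambda[i]) / (n * (1 - lambda[i]))
      }, numeric(1))
      mean((boots - min_pi0)^2)
    }, numeric(1))
    pi0_l[which.min(mse)]
  }
  1 - min(max(pi0, 0), 1)
}
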