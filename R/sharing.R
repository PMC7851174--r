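## Cross-tissue sharing and specificity analytics. Tissue result tables are
## data frames with variant_id, gene_id, md, fdr_q, significant (as produced
## by simulate_multitissue() or assembled from per-tissue scans).

.pair_key <- function(df) paste(df$variant_id, df$gene_id, sep = "|")

#' Effect-size correlation between two tissues
#'
#' Restricts to variant-gene pairs tested in both tissues and significant in
#' at least one, then computes the Pearson correlation of their MD values.
#'
#' @param t1,t2 Tissue result data frames (`variant_id`, `gene_id`, `md`,
#'   `significant`).
#' @return Pearson r, or `NaN` (with a warning) when fewer than 3 shared
#'   pairs qualify.
#' @export
sharing_corr <- function(t1, t2) {
  k1 <- .pair_key(t1); k2 <- .pair_key(t2)
  common <- intersect(k1, k2)
  i1 <- match(common, k1); i2 <- match(common, k2)
  keep <- t1$significant[i1] | t2$significant[i2]
  if (sum(keep) < 3) {
    warning("fewer than 3 shared significant pairs; returning NaN")
    return(NaN)
  }
  cor(t1$md[i1][keep], t2$md[i2][keep])
}

#' Jaccard index of significant variant-gene pairs
#'
#' @param t1,t2 Tissue result data frames.
#' @return `|A intersect B| / |A union B|`; 0 when the union is empty.
#' @export
jaccard_sharing <- function(t1, t2) {
  a <- .pair_key(t1[t1$significant, , drop = FALSE])
  b <- .pair_key(t2[t2$significant, , drop = FALSE])
  u <- union(a, b)
  if (length(u) == 0) return(0)
  length(intersect(a, b)) / length(u)
}

#' Tissue specificity from a pairwise similarity matrix
#'
#' For each tissue `t`, specificity is \eqn{s_t = 1 - \bar r_t}, where
#' \eqn{\bar r_t} is the mean off-diagonal similarity (MD correlation or
#' Jaccard) between `t` and the other tissues.
#'
#' @param sim Square similarity matrix with tissue dimnames.
#' @return Named numeric vector of specificities.
#' @export
tissue_specificity <- function(sim) {
  sim <- as.matrix(sim)
  n <- nrow(sim)
  if (n < 2) stop_format("need at least 2 tissues")
  s <- vapply(seq_len(n), function(i) 1 - mean(sim[i, -i]), numeric(1))
  names(s) <- rownames(sim)
  s
}

#' Centroid-based distance between two tissues
#'
#' Compares whole splicing-phenotype changes: for each shared variant-gene
#' pair `j` and dosage group `k`, the centroid of the adjusted (square-root
#' transformed, covariate-corrected) splicing ratios is computed per tissue;
#' the tissue distance is the mean over pairs of the summed Euclidean
#' distances between matching centroids,
#' \eqn{d(t_1,t_2) = \frac1p \sum_j \sum_k \lVert c_{t_1jk} - c_{t_2jk}\rVert}.
#' Small distances mean high sharing. Pairs must be present in both tissues
#' with identical transcript sets; a dosage group observed in exactly one
#' tissue drops the pair (conservative), while groups absent from both
#' contribute zero.
#'
#' @param c1,c2 Centroid sets: named lists (one element per variant-gene
#'   pair) of lists indexed by dosage group (`"0"`, `"1"`, `"2"`) holding
#'   centroid vectors (or `NULL` for unobserved groups).
#' @return The distance (non-negative scalar).
#' @export
centroid_distance <- function(c1, c2) {
  pairs <- names(c1)
  if (!setequal(pairs, names(c2))) stop_format("mismatched pair universe")
  total <- 0
  used <- 0L
  for (j in pairs) {
    a <- c1[[j]]; b <- c2[[j]]
    groups <- union(names(a), names(b))
    contrib <- 0
    ok <- TRUE
    for (k in groups) {
      ak <- a[[k]]; bk <- b[[k]]
      if (is.null(ak) && is.null(bk)) next
      if (is.null(ak) || is.null(bk)) { ok <- FALSE; break }
      if (length(ak) != length(bk)) {
        stop_format("pair %s: centroid dimensions differ", j)
      }
      contrib <- contrib + sqrt(sum((ak - bk)^2))
    }
    if (ok) {
      total <- total + contrib
      used <- used + 1L
    }
  }
  if (used == 0) stop_format("no comparable pairs")
  total / used
}

#' Centroids of the adjusted phenotype per dosage group
#'
#' @param pheno An `"adjusted_phenotype"` object.
#' @param dosage Dosage vector aligned with the phenotype samples.
#' @return A list indexed by dosage group of centroid vectors.
#' @export
phenotype_centroids <- function(pheno, dosage) {
  stopifnot(inherits(pheno, "adjusted_phenotype"))
  use <- dosage >= 0
  Y <- pheno$matrix[use, , drop = FALSE]
  d <- dosage[use]
  out <- list()
  for (k in sort(unique(d))) {
    out[[as.character(k)]] <- colMeans(Y[d == k, , drop = FALSE])
  }
  out
}

#' Baker's Gamma between two dendrograms
#'
#' Rank correlation between the stages at which pairs of leaves first
#' combine in each tree, computed as the Spearman correlation of cophenetic
#' merge heights (rank-equivalent to merge stages within a tree).
#' Significance comes from shuffling the leaf labels of one tree
#' `n_perm` times, keeping both topologies constant.
#'
#' @param h1,h2 `"hclust"` objects over the same label set (>= 4 leaves).
#' @param n_perm Label shuffles for the permutation p-value (default 10000;
#'   0 skips the test).
#' @param seed Optional integer seed.
#' @return A list with `gamma` and (when `n_perm > 0`) `p` and `null_gamma`.
#' @export
bakers_gamma <- function(h1, h2, n_perm = 10000L, seed = NULL) {
  if (!setequal(h1$labels, h2$labels)) stop_format("leaf-set mismatch")
  if (length(h1$labels) < 4) stop_format("need at least 4 leaves")
  d1 <- as.matrix(cophenetic(h1))
  d2 <- as.matrix(cophenetic(h2))
  labs <- h1$labels
  d2 <- d2[labs, labs]
  lower <- lower.tri(d1)
  g_of <- function(m2) cor(d1[lower], m2[lower], method = "spearman")
  gamma <- g_of(d2)
  if (n_perm <= 0) return(list(gamma = gamma))
  null_gamma <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      sh <- sample(labs)
      m2 <- d2
      dimnames(m2) <- list(sh, sh)
      g_of(m2[labs, labs])
    }, numeric(1))
  })
  p <- (1 + sum(null_gamma >= gamma)) / (1 + n_perm)
  list(gamma = gamma, p = p, null_gamma = null_gamma)
}

#' Hierarchical clustering of tissues and dendrogram comparison
#'
#' Clusters tissues from one or more distance matrices (average linkage by
#' default, the linkage being configurable) and, when two matrices are
#' given, compares the resulting dendrograms with Baker's Gamma.
#'
#' @param d1 Distance matrix (or `"dist"`) between tissues.
#' @param d2 Optional second distance matrix over the same tissues.
#' @param method Linkage method for [stats::hclust()].
#' @param n_perm Permutations for the Baker's Gamma test.
#' @param seed Optional integer seed.
#' @return A list with `tree1` and, if `d2` is given, `tree2`, `gamma`, `p`.
#' @export
cluster_and_compare <- function(d1, d2 = NULL, method = "average",
                                n_perm = 10000L, seed = NULL) {
  t1 <- hclust(as.dist(d1), method = method)
  if (is.null(d2)) return(list(tree1 = t1))
  t2 <- hclust(as.dist(d2), method = method)
  bg <- bakers_gamma(t1, t2, n_perm = n_perm, seed = seed)
  list(tree1 = t1, tree2 = t2, gamma = bg$gamma, p = bg$p)
}

#' Export a dendrogram in Newick format
#'
#' @param h An `"hclust"` object (e.g. from [cluster_and_compare()]).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_newick <- function(h, path) {
  ape::write.tree(ape::as.phylo(h), file = path)
  invisible(path)
}

#' Tissue-specificity tau index
#'
#' \eqn{\tau = \sum_t (1 - \hat x_t) / (n - 1)} with
#' \eqn{\hat x_t = x_t / \max_t x_t}: 0 for uniform profiles, 1 for
#' one-tissue profiles. For expression, `x` is median gene expression per
#' tissue; for the splicing variant (tau_s), `x` is \eqn{-\log_{10}} of the
#' sGene FDR per tissue, capped at 300 to avoid underflow infinities.
#'
#' @param x Non-negative per-tissue values (length >= 2, max > 0).
#' @param basis `"expression"` (values used as given) or `"splicing"`
#'   (values taken as FDR q-values and transformed to capped -log10).
#' @return tau in \[0, 1\].
#' @examples
#' tau_index(c(1, 0.5))
#' @export
tau_index <- function(x, basis = c("expression", "splicing")) {
  basis <- match.arg(basis)
  if (basis == "splicing") x <- pmin(-log10(x), 300)
  if (length(x) < 2) stop_format("need values for >= 2 tissues")
  if (any(x < 0)) stop_format("values must be non-negative")
  if (max(x) <= 0) stop_format("all-zero profile")
  xhat <- x / max(x)
  sum(1 - xhat) / (length(x) - 1)
}

#' Select tissue-specific / ubiquitous genes by tau percentiles
#'
#' Utility filter: returns the names of entries in the top (or bottom)
#' `percent` percentile of a tau value vector.
#'
#' @param tau Named numeric vector of tau (or tau_s) values.
#' @param percent Percentile width in (0, 100).
#' @param top `TRUE` for the top tail, `FALSE` for the bottom.
#' @return Character vector of names.
#' @export
tau_percentile <- function(tau, percent = 20, top = TRUE) {
  q <- if (top) quantile(tau, 1 - percent / 100) else quantile(tau, percent / 100)
  names(tau)[if (top) tau >= q else tau <= q]
}
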