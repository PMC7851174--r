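# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code; no data files.

# small expression table: 2 genes x (2,3) transcripts, named samples
toy_expression <- function() {
  tpm <- rbind(
    g1_t1 = c(2, 4, 6),
    g1_t2 = c(2, 4, 2),
    g2_t1 = c(1, 1, 1),
    g2_t2 = c(3, 1, 0.5),
    g2_t3 = c(0.05, 0.04, 0.02)
  )
  colnames(tpm) <- c("S1", "S2", "S3")
  expression_table(rownames(tpm), c("g1", "g1", "g2", "g2", "g2"), tpm)
}

toy_genotypes <- function(n_samples = 3) {
  variants <- data.frame(variant_id = c("v1", "v2"),
                         chrom = "chr1", start = c(100L, 5000L),
                         end = c(101L, 5001L), ref = "A", alt = "G",
                         stringsAsFactors = FALSE)
  dos <- matrix(c(0L, 1L, 2L, 1L, 1L, 0L)[seq_len(2 * n_samples)],
                nrow = 2, byrow = TRUE,
                dimnames = list(NULL, paste0("S", seq_len(n_samples))))
  genotype_table(variants, dos)
}

# adjusted null phenotype + balanced dosage groups for permutation tests
null_phenotype <- function(n, tx = 3, groups = c(0.49, 0.42, 0.09), seed = 1) {
  withr::local_seed(seed)
  ratios <- matrix(rgamma(n * tx, shape = 5), n, tx)
  ratios <- ratios / rowSums(ratios)
  g <- factor(sample(rep(0:2, round(groups * n))[seq_len(n)]))
  Y <- sqrt(ratios)
  Y <- sweep(Y, 2, colMeans(Y))
  list(Y = Y, g = g, ratios = ratios)
}

# independent pseudo-F oracle straight from the definitional sums of
# squared distances (no Gower centering, no group-sum algebra)
oracle_pseudo_f <- function(d, groups) {
  D2 <- as.matrix(d)^2
  g <- factor(groups)
  n <- nrow(D2)
  k <- nlevels(g)
  sst <- sum(D2[upper.tri(D2)]) / n
  ssw <- 0
  for (lev in levels(g)) {
    idx <- which(g == lev)
    sub <- D2[idx, idx, drop = FALSE]
    ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ssb <- sst - ssw
  (ssb / (k - 1)) / (ssw / (n - k))
}

# independent exhaustive enumeration oracle for two-group exact p-values:
# all C(n, n1) assignments, p = #{F >= F_obs} / N (observed included)
oracle_exact_p_2groups <- function(Y, g) {
  g <- factor(g)
  n <- nrow(Y)
  idx1 <- utils::combn(n, sum(g == levels(g)[1]))
  d <- dist(Y)
  fobs <- oracle_pseudo_f(d, g)
  fs <- apply(idx1, 2, function(ii) {
    gl <- rep(levels(g)[2], n)
    gl[ii] <- levels(g)[1]
    oracle_pseudo_f(d, gl)
  })
  sum(fs >= fobs - 1e-12) / ncol(idx1)
}

# simulate one gene end to end and return its adjusted phenotype + dosage
sim_gene <- function(n = 150, effect_md = 0, seed = 1, tx = 3) {
  sp <- simulation_spec(n_samples = n, n_genes = 1, transcripts_per_gene = tx,
                        effect_md = effect_md,
                        frac_sgenes = as.numeric(effect_md > 0), seed = seed)
  gt <- simulate_genotypes(sp)
  sim <- simulate_splicing(sp, gt)
  r <- compute_ratios(sim$expression, "gene1")
  if (!identical(r$status, "ok")) return(NULL)
  ph <- adjust_covariates(r)
  d <- gt$dosages[1, ph$samples]
  if (length(unique(d)) < 2 || min(table(d)) < 10) return(NULL)
  list(ph = ph, dosage = d, truth = sim$truth, ratios = r)
}

tx_struct <- function(id, strand, ...) {
  transcript_structure(id, strand, rbind(...))
}
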