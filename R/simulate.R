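## Synthetic cohorts with the statistical structure the association test
## assumes: Hardy-Weinberg biallelic genotypes, per-gene Dirichlet splicing
## ratios whose means shift with dosage by a calibrated maximum difference
## (MD), lognormal gene expression, optional covariate effects on the
## square-root-ratio scale, and multi-tissue effect-size tables with tunable
## cross-tissue correlation.

#' Specification of a synthetic splicing cohort
#'
#' Bundles every tunable of the generator; the seed fully determines the
#' output. Defaults describe a realistic single-tissue cohort: common
#' variants (MAF 0.3, keeping all three dosage groups testable at moderate
#' n), three isoforms per gene, Dirichlet concentration 20 (per-sample ratio
#' noise with SD around 0.1), moderate effect sizes.
#'
#' @param n_samples Number of samples.
#' @param n_genes Number of genes.
#' @param transcripts_per_gene Isoforms per gene (>= 2 for simulation).
#' @param maf Minor allele frequency in (0, 0.5].
#' @param effect_md Target MD (maximum difference between the population
#'   mean splicing ratios of the homozygous dosage groups), in \[0, 1\].
#' @param frac_sgenes Proportion of genes carrying a true effect.
#' @param dirichlet_concentration Dirichlet concentration of the per-sample
#'   ratios around their genotype-group mean (> 0).
#' @param covariates Optional list of covariate specs, each a list with
#'   `name`, `type` (`"numeric"` or `"categorical"`) and `effect`
#'   (additive effect on the sqrt-ratio scale).
#' @param seed Integer seed.
#' @return An object of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_samples, n_genes = 1L, transcripts_per_gene = 3L,
                            maf = 0.3, effect_md = 0.2, frac_sgenes = 1,
                            dirichlet_concentration = 20,
                            covariates = NULL, seed = 1L) {
  if (n_samples < 1) stop_format("n_samples must be >= 1")
  if (maf <= 0 || maf > 0.5) stop_format("maf must lie in (0, 0.5]")
  if (effect_md < 0 || effect_md > 1) stop_format("effect_md must lie in [0, 1]")
  if (dirichlet_concentration <= 0) stop_format("dirichlet_concentration must be > 0")
  if (frac_sgenes < 0 || frac_sgenes > 1) stop_format("frac_sgenes must lie in [0, 1]")
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 transcripts_per_gene = as.integer(transcripts_per_gene),
                 maf = maf, effect_md = effect_md, frac_sgenes = frac_sgenes,
                 dirichlet_concentration = dirichlet_concentration,
                 covariates = covariates, seed = as.integer(seed)),
            class = "simulation_spec")
}

.sim_samples <- function(n) sprintf("S%04d", seq_len(n))
.sim_genes <- function(n) sprintf("gene%d", seq_len(n))

## deterministic synthetic genome layout: genes on chr1, 10 kb bodies
## spaced 50 kb apart, the tested variant mid-gene
.sim_gene_coords <- function(g) {
  start <- (g - 1L) * 50000L + 10000L
  list(chrom = "chr1", start = start, end = start + 10000L,
       variant_pos = start + 5000L)
}

#' Simulate Hardy-Weinberg genotypes
#'
#' One biallelic variant per gene, dosages drawn Binomial(2, maf), placed
#' mid-gene on the synthetic chromosome layout shared with
#' [simulate_gene_annotation()].
#'
#' @param spec A [simulation_spec()].
#' @return A [genotype_table()].
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(child_seed(spec$seed, "genotypes"), {
    n <- spec$n_samples
    dos <- matrix(rbinom(n * spec$n_genes, 2L, spec$maf),
                  nrow = spec$n_genes, byrow = TRUE,
                  dimnames = list(NULL, .sim_samples(n)))
    coords <- lapply(seq_len(spec$n_genes), .sim_gene_coords)
    variants <- data.frame(
      variant_id = sprintf("var%d", seq_len(spec$n_genes)),
      chrom = vapply(coords, `[[`, character(1), "chrom"),
      start = vapply(coords, `[[`, numeric(1), "variant_pos"),
      end = vapply(coords, `[[`, numeric(1), "variant_pos") + 1L,
      ref = "A", alt = "G", stringsAsFactors = FALSE)
    genotype_table(variants, dos)
  })
}

#' Synthetic gene annotation matching the simulated layout
#'
#' Each gene gets `transcripts_per_gene` isoforms differing by a cassette
#' exon and an alternative acceptor, so downstream event classification has
#' something to classify.
#'
#' @param spec A [simulation_spec()].
#' @return A `"gene_annotation"` object.
#' @export
simulate_gene_annotation <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  genes <- do.call(rbind, lapply(seq_len(spec$n_genes), function(g) {
    co <- .sim_gene_coords(g)
    data.frame(gene_id = .sim_genes(spec$n_genes)[g], chrom = co$chrom,
               start = co$start, end = co$end, strand = "+",
               stringsAsFactors = FALSE)
  }))
  transcripts <- lapply(seq_len(spec$n_genes), function(g) {
    co <- .sim_gene_coords(g)
    s <- co$start
    base <- list(c(s, s + 1000), c(s + 3000, s + 4000), c(s + 8000, s + 10000))
    txs <- list(
      transcript_structure(sprintf("g%d_t1", g), "+", do.call(rbind, base)),
      transcript_structure(sprintf("g%d_t2", g), "+",
                           rbind(base[[1]], base[[3]])))
    extra <- spec$transcripts_per_gene - 2L
    if (extra > 0) {
      for (j in seq_len(extra)) {
        alt <- base
        alt[[2]][1] <- alt[[2]][1] + 200 * j  # shifted acceptor
        txs[[2L + j]] <- transcript_structure(sprintf("g%d_t%d", g, j + 2L),
                                              "+", do.call(rbind, alt))
      }
    }
    txs
  })
  names(transcripts) <- .sim_genes(spec$n_genes)
  structure(list(genes = genes, transcripts = transcripts),
            class = "gene_annotation")
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

## shift a mean composition toward `target` by shrinking the others
## proportionally; clipped at zero and renormalized
.shift_mean <- function(m0, target, s) {
  m <- m0
  m[target] <- m[target] + s
  rest <- setdiff(seq_along(m), target)
  m[rest] <- m[rest] - s * m0[rest] / sum(m0[rest])
  m <- pmax(m, 0)
  m / sum(m)
}

## dosage-group mean compositions: heterozygotes sit at m0, homozygotes are
## shifted symmetrically by +/- s/2 toward/away from the target transcript
.dosage_means <- function(m0, target, s) {
  lapply(0:2, function(d) .shift_mean(m0, target, s * (d - 1) / 2))
}

## 1-D root finding for the shift whose realized MD between the extreme
## dosage-group mean compositions equals the target; clipping at the
## simplex boundary makes the map non-linear, hence numerical inversion
.calibrate_shift <- function(m0, target, md) {
  if (md == 0) return(0)
  realized <- function(s) {
    m <- .dosage_means(m0, target, s)
    max(abs(m[[3]] - m[[1]]))
  }
  s_max <- 2
  if (md >= realized(s_max) - 1e-12) return(s_max)
  uniroot(function(s) realized(s) - md, c(0, s_max), tol = 1e-10)$root
}

#' Simulate splicing phenotypes with genotype-dependent composition shifts
#'
#' For each gene, per-sample splicing ratios are Dirichlet around a
#' dosage-group mean composition. For true sGenes the mean composition
#' shifts linearly with dosage so that the population MD between the two
#' homozygous group means equals `effect_md` (calibrated by 1-D root
#' finding, since clipping at the simplex boundary makes the map
#' non-linear). TPMs are the ratios scaled by a lognormal gene expression.
#' Covariate effects act additively on the sqrt-ratio scale and the
#' composition is renormalized.
#'
#' @param spec A [simulation_spec()].
#' @param genotypes The [genotype_table()] from [simulate_genotypes()] for
#'   the same spec.
#' @return A list: `expression` (an [expression_table()]), `truth` (data
#'   frame `gene_id`, `variant_id`, `is_sgene`, `target_md`), `covariates`
#'   (data frame or `NULL`), `group_means` (list of true per-dosage mean
#'   compositions).
#' @export
simulate_splicing <- function(spec, genotypes) {
  stopifnot(inherits(spec, "simulation_spec"),
            inherits(genotypes, "genotype_table"))
  if (spec$transcripts_per_gene < 2) stop_format("transcripts_per_gene must be >= 2")
  with_seed(child_seed(spec$seed, "splicing"), {
    n <- spec$n_samples
    Tn <- spec$transcripts_per_gene
    samples <- .sim_samples(n)
    gene_ids <- .sim_genes(spec$n_genes)
    n_sgenes <- round(spec$frac_sgenes * spec$n_genes)
    sgenes <- if (n_sgenes > 0) sort(sample.int(spec$n_genes, n_sgenes)) else integer(0)

    cov_df <- NULL
    cov_effects <- list()
    if (!is.null(spec$covariates)) {
      cov_df <- data.frame(row.names = samples)
      for (cv in spec$covariates) {
        if (identical(cv$type, "categorical")) {
          val <- factor(sample(c("a", "b"), n, replace = TRUE))
          num <- as.numeric(val) - 1.5
        } else {
          val <- rnorm(n)
          num <- val
        }
        cov_df[[cv$name]] <- val
        cov_effects[[cv$name]] <- list(beta = cv$effect, x = num)
      }
    }

    tpm <- matrix(0, nrow = spec$n_genes * Tn, ncol = n,
                  dimnames = list(NULL, samples))
    tx_ids <- character(spec$n_genes * Tn)
    tx_gene <- character(spec$n_genes * Tn)
    group_means <- vector("list", spec$n_genes)
    names(group_means) <- gene_ids

    for (g in seq_len(spec$n_genes)) {
      m0 <- as.numeric(.rdirichlet(1, rep(2, Tn)))
      ## keep the shifted transcript away from the boundary
      target <- which.max(m0)
      is_s <- g %in% sgenes
      s_full <- if (is_s) .calibrate_shift(m0, target, spec$effect_md) else 0
      dos <- genotypes$dosages[g, samples]
      means <- .dosage_means(m0, target, s_full)
      group_means[[g]] <- means
      ratios <- matrix(0, n, Tn)
      for (d in 0:2) {
        idx <- which(dos == d)
        if (length(idx)) {
          ratios[idx, ] <- .rdirichlet(length(idx),
                                       spec$dirichlet_concentration * means[[d + 1]])
        }
      }
      if (length(cov_effects)) {
        sq <- sqrt(ratios)
        for (ce in cov_effects) {
          sq[, 1] <- sq[, 1] + ce$beta * ce$x
        }
        sq <- pmax(sq, 0)
        ratios <- sq^2 / rowSums(sq^2)
      }
      expr_level <- rlnorm(n, meanlog = log(50), sdlog = 1)
      rows <- (g - 1L) * Tn + seq_len(Tn)
      tpm[rows, ] <- t(ratios * expr_level)
      tx_ids[rows] <- sprintf("g%d_t%d", g, seq_len(Tn))
      tx_gene[rows] <- gene_ids[g]
    }

    truth <- data.frame(gene_id = gene_ids,
                        variant_id = genotypes$variants$variant_id,
                        is_sgene = seq_len(spec$n_genes) %in% sgenes,
                        target_md = ifelse(seq_len(spec$n_genes) %in% sgenes,
                                           spec$effect_md, 0),
                        stringsAsFactors = FALSE)
    if (!is.null(cov_df)) cov_df <- data.frame(sample_id = samples, cov_df)
    list(expression = expression_table(tx_ids, tx_gene, tpm),
         truth = truth, covariates = cov_df, group_means = group_means)
  })
}

#' Simulate per-tissue effect-size tables with tunable sharing
#'
#' Variant-gene pair MD values are drawn from a Gaussian copula with
#' equicorrelation `sharing` across tissues, mapped linearly to a realistic
#' MD scale (mean 0.25, SD 0.05, clipped to \[0.01, 0.49\]); the linear map
#' preserves the Pearson correlation. Significance flags and FDR q-values
#' are generated per tissue.
#'
#' @param spec A [simulation_spec()]; `n_genes` sets the number of pairs
#'   unless `n_pairs` is given.
#' @param n_tissues Number of tissues.
#' @param sharing Target pairwise MD correlation in \[0, 1\].
#' @param n_pairs Number of variant-gene pairs.
#' @return Named list (one element per tissue) of data frames with
#'   `variant_id`, `gene_id`, `md`, `fdr_q`, `significant`.
#' @export
simulate_multitissue <- function(spec, n_tissues, sharing,
                                 n_pairs = spec$n_genes) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (sharing < 0 || sharing > 1) stop_format("sharing must lie in [0, 1]")
  with_seed(child_seed(spec$seed, "multitissue"), {
    common <- rnorm(n_pairs)
    out <- lapply(seq_len(n_tissues), function(t) {
      z <- sqrt(sharing) * common + sqrt(1 - sharing) * rnorm(n_pairs)
      md <- pmin(pmax(0.25 + 0.05 * z, 0.01), 0.49)
      fdr_q <- 10^(-pmax(0, (md - 0.05) * 30 * runif(n_pairs, 0, 2)))
      data.frame(variant_id = sprintf("var%d", seq_len(n_pairs)),
                 gene_id = sprintf("gene%d", seq_len(n_pairs)),
                 md = md, fdr_q = fdr_q,
                 significant = fdr_q < 0.05 & md >= 0.05,
                 stringsAsFactors = FALSE)
    })
    names(out) <- sprintf("tissue%d", seq_len(n_tissues))
    out
  })
}
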