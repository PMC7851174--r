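---
title: "Methods: multivariate splicing-QTL mapping with sqtlmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multivariate splicing-QTL mapping with sqtlmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sqtlmap)
```

## The model

A gene with $T$ expressed isoforms has, in each sample, a *splicing ratio*
vector: the transcript TPMs divided by their sum. This phenotype is
compositional — non-negative, summing to one — and multivariate, so
`sqtlmap` tests genetic association against the whole vector rather than
against each isoform separately. Variability between two samples $x$ and
$y$ is measured with the Hellinger distance

$$ H(x, y) = \sqrt{\tfrac12 \sum_{i=1}^{T} (\sqrt{x_i} - \sqrt{y_i})^2}
\in [0, 1], $$

a proper metric on the simplex that equals the Euclidean distance between
square-rooted compositions up to a factor $1/\sqrt2$. That identity is the
backbone of the implementation: every downstream computation operates on
the square-root scale, where Hellinger geometry is Euclidean geometry.

Association between genotype dosage (groups $k = 0, 1, 2$) and the
phenotype uses Anderson's distance-based pseudo-F, a non-parametric
analogue of MANOVA. With $G = -\tfrac12 J (D \circ D) J$ the Gower-centered
matrix of squared distances and $H$ the hat matrix of group indicators,

$$ F = \frac{\mathrm{tr}(HGH)/(k-1)}{\mathrm{tr}((I-H)G(I-H))/(n-k)}. $$

Because the distances are Euclidean on the adjusted matrix, the traces
reduce to ordinary between/within sums of squares of group means, which is
how the permutation engine evaluates tens of thousands of label
permutations cheaply (`pseudo_f()` keeps both routes and the test suite
asserts their equality, including against an established PERMANOVA
implementation).

## Filters and covariates

The preprocessing defaults mirror standard sQTL practice: a gene enters
the analysis if its total TPM is at least 1 in at least 80% of samples
(samples below that threshold are dropped for that gene only), it has at
least two isoforms, and isoforms never reaching 0.1 TPM are removed, with
ratios renormalized over the retained set. Variants are tested in the gene
body plus 5 kb on each side, and must be biallelic with MAF at least 0.01
and at least 10 samples in every observed dosage group; samples with
missing dosage are dropped per variant and the rules re-checked.

Covariates are regressed out per transcript coordinate on the square-root
scale (categoricals one-hot encoded, reference level dropped) and the
residual matrix is the adjusted phenotype. Residualizing on the square-root
scale — rather than on raw ratios — keeps the distance self-consistent:
Euclidean distance on the residuals is exactly the covariate-corrected
Hellinger distance. The raw-versus-sqrt choice is not dictated by the
method's public description; we chose the sqrt scale for this
self-consistency and document it as a package decision.

## Significance

Three nominal p-value modes share one contract (ties count against
significance, p-values never return 0):

* `exact_perm` enumerates all distinct label arrangements (up to $10^5$)
  and counts arrangements with $F \ge F_{obs}$, the observed one included.
* `mc_perm` uses $B$ random permutations with the $(1+\text{hits})/(1+B)$
  estimator.
* `approx` (default) fits a moment-matched Pearson-III (shifted gamma)
  right tail to an initial batch of $B_0$ permutation F values and returns
  its upper-tail probability, floored at the smallest positive double.

The fit is two-stage. Moment estimates (mean, variance, skewness) from
the first batch of $B_0 = 500$ permutations suffice wherever the p-value
is moderate, but their noise propagates multiplicatively into the far
tail; so whenever the first-stage p-value falls below 0.02 the batch is
extended to 5,000 permutations and refit. This keeps null scans — the
bulk of any cis scan — at the cheap batch size while giving the
tail-sensitive minority the accuracy needed to track the brute-force
permutation p-value within about 0.3 log10 units down to
$p \approx 10^{-4}$, the fidelity the validation suite audits. The
permutation modes remain the ground-truth path and arbitrate the
approximation in the tests.

Because the pseudo-F is sensitive to heterogeneity of within-group
dispersion, every pair is also screened with a multivariate
homogeneity-of-dispersions test: each sample's distance to its own group
centroid in the adjusted space, a one-way ANOVA F on those distances, and
a permutation p-value obtained by shuffling group labels over the fixed
distance vector (the same convention as the established `betadisper`
permutation test, against which the statistic is cross-checked). Pairs
failing the screen at BH FDR < 0.05 across all nominal tests are flagged,
kept in multiple-testing correction, and never reported as significant.

## Gene-level correction and pair retrieval

Multiple variants per gene are handled by an adaptive permutation scheme:
phenotype rows are permuted jointly, the minimum nominal p across the
gene's variants is recorded per permutation, and permutation stops once 10
permutation minima fall at or below the observed minimum (with at least
100 and at most 1,000 permutations; all three constants are arguments).
A key economy: under label permutation the null distribution of a
variant's F is invariant, so each variant's Pearson-III tail fit is
computed once and reused across all phenotype permutations. The empirical
p-value is $(1+\text{hits})/(1+B)$, and a method-of-moments Beta fit to
the permutation minima supports threshold interpolation.

sGenes are called by BH FDR (default 0.05) on the empirical p-values. To
retrieve all significant pairs, the genome-wide threshold $p_t$ is the
midpoint between the largest passing and smallest failing empirical
p-value; each sGene's nominal threshold is the $p_t$ quantile of its
permutation-minimum distribution (Beta quantile when the fit is valid,
empirical quantile otherwise). Reported pairs must also have effect size
MD $\ge$ 0.05 and pass the homoscedasticity screen.

The effect size MD is the absolute maximum difference in mean adjusted
transcript relative expression between dosage groups, over transcripts and
group pairs; it lives in $[0,1]$. Residuals are sqrt-scale, so adjusted
relative expression is reconstructed per sample as
$(\text{residual} + \overline{\sqrt{r}})^2$, clipped to $[0,1]$; with no
covariates this reproduces the raw ratios exactly, which pins down the
back-transformation that the method's public description leaves open.

Replication is summarised by $\pi_1 = 1 - \hat\pi_0$ with the
$\lambda$-grid estimator ($\hat\pi_0(\lambda)$ smoothed by a cubic spline
and read at $\lambda = 0.95$; a bootstrap single-$\lambda$ choice below
100 p-values). The estimator is implemented in-package because no
pre-packaged q-value machinery is assumed.

## Sharing, events, enrichment

Cross-tissue analytics operate on per-tissue result tables restricted to
comparable pairs: Pearson correlation of MD values and the Jaccard index
of significant pair sets (both over pairs tested in both tissues,
significant in at least one), tissue specificity $s_t = 1 - \bar r_t$, and
a geometric tissue distance — the mean over variant-gene pairs of the
summed Euclidean distances between per-dosage centroids of the adjusted
phenotype. Pairs whose transcript sets differ between tissues, or with a
dosage group observed in exactly one tissue, are dropped (conservative;
the alternative of zero-filling would understate distances). Dendrograms
(average linkage by default; configurable, as no linkage is canonical)
are compared with Baker's Gamma, computed as the Spearman correlation of
cophenetic merge heights — rank-equivalent to merge stages — with a
10,000-shuffle label permutation test. The $\tau$ index uses per-tissue
median expression; its splicing variant $\tau_s$ uses $-\log_{10}$ FDR
capped at 300 to avoid underflow infinities.

Event classification compares the exon chains of the two isoforms that
change most in opposite directions across the MD-achieving group pair.
Boundaries shared by both isoforms (same coordinate, same side; compared
exactly, no fuzz) delimit variable regions; each region's pattern of
isoform-specific boundaries maps to exon skipping, alternative
donor/acceptor (strand-aware), intron retention, mutually exclusive
exons, alternative or tandem termini, with `complex_*` as the documented
catch-all for any unmatched pattern — the boundary between "complex" and
stacked simple events is a versioned package rule, not an external
standard.

Functional enrichment compares sQTLs (top 10 per gene) against 1,000 null
sets of non-sQTLs matched on MAF ($\pm 0.02$) and gene-relative location
bin (the same 20-bin scheme as the positional profiles, unified for
coherence). Null sets are drawn without replacement within a set and with
replacement across sets. The odds ratio is formed against the mean null
annotated count, rounded half-up, with a two-sided Fisher test on the raw
table; tracks with mean null count below 5 are dropped.

## What the simulator emulates — and what it does not

`simulation_spec()` fixes the study conditions: Hardy-Weinberg biallelic
dosages at MAF 0.3 (keeping all three dosage groups above the 10-sample
rule at moderate cohort sizes), three isoforms per gene, per-sample ratios
Dirichlet-distributed around dosage-group means with concentration 20
(per-coordinate noise SD near 0.1, a realistic splicing-ratio spread),
lognormal gene expression (median 50 TPM), and optional covariates acting
additively on the sqrt-ratio scale. Effects shift the group-mean
composition toward one transcript symmetrically around the heterozygote;
the shift is calibrated by 1-D root finding so the population MD between
homozygous group means equals the target exactly even when clipping at
the simplex boundary bends the map. Multi-tissue MD tables come from a
Gaussian copula with equicorrelation equal to the requested sharing,
mapped linearly (hence correlation-preserving) to a realistic MD scale.

The simulator does not emulate linkage disequilibrium between variants,
read-level quantification noise (TPM estimation error, mapping bias),
cell-type heterogeneity, or non-Dirichlet ratio distributions. Passing
tests therefore demonstrate the statistical machinery — calibration,
fidelity, recovery, FDR control — under the model's own assumptions, not
robustness to quantification artifacts in real data.

## Numerical choices and problem sizes

Degenerate dispersion (all phenotypes identical) yields `NaN` with a
`degenerate` flag rather than an error; degenerate homoscedasticity
returns p = 1 with a flag. F-value comparisons use a $10^{-12}$ absolute
tie tolerance in favour of the null. Collinear covariate columns are
dropped with a warning via the QR rank. The validation suite uses cohorts
of 150–200 samples and 200–1,200 genes — sizes at which group means are
stable under the 10-per-group rule and the binomial error bands of the
calibration checks are tight — and a brute-force permutation depth of
$10^5$ where the approximation is audited.

## Limitations

Only cis, single-variant, genotype-group tests are provided (no
interactions, haplotypes, or trans scans). The gene-level scheme assumes
exchangeable samples under the null; strong population structure must be
handled through the covariates. The Pearson-III tail is an approximation:
far beyond $p \sim 10^{-6}$ its accuracy is unverifiable by permutation
and should be treated as an ordering device, as in any permutation-based
xQTL pipeline. Event classification relies on exact coordinate matches
and thus on a consistent annotation source.
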