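Package: sqtlmap
Title: Multivariate Splicing QTL Mapping via Hellinger-Distance PERMANOVA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps cis splicing quantitative trait loci (sQTLs) by testing
    genetic variants for association with the multivariate vector of a gene's
    transcript relative abundances. The test is a distance-based pseudo-F
    (Anderson's non-parametric MANOVA analogue) on Hellinger distances between
    splicing-ratio profiles, with exact, Monte-Carlo and moment-matched
    approximate permutation p-values, a multivariate homoscedasticity screen,
    and an adaptive-permutation gene-level multiple-testing correction with
    significant-pair retrieval. Includes effect-size estimation (maximum
    difference in mean adjusted transcript relative expression), pi1
    replication estimates, cross-tissue sharing and tissue-specificity
    analytics (effect-size correlation, Jaccard, centroid distance, Baker's
    Gamma, tau indices), alternative-splicing event classification from
    transcript exon structures, matched-null functional enrichment, positional
    profiles, heteropleiotropy calling, splice-site PWM delta scoring, and a
    synthetic-data generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    rtracklayer,
    GenomicRanges,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse,
    jsonlite
Config/testthat/edition: 3
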