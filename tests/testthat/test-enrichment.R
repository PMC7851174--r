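test_that("matched-null sampling honours bin and MAF constraints", {
  set.seed(71)
  sqtls <- data.frame(variant_id = paste0("s", 1:5),
                      maf = c(0.10, 0.25, 0.40, 0.05, 0.30),
                      bin = c(3L, 3L, 7L, 1L, 7L))
  candidates <- data.frame(variant_id = paste0("c", 1:400),
                           maf = runif(400, 0.01, 0.5),
                           bin = sample(c(1L, 3L, 7L), 400, replace = TRUE))
  spec <- matched_null_spec(n_sets = 50)
  sets <- sample_matched_null(sqtls, candidates, spec, seed = 1)
  expect_length(sets, 50)
  for (s in sets) {
    expect_length(s, 5)
    expect_false(anyDuplicated(s) > 0)  # without replacement within a set
    idx <- match(s, candidates$variant_id)
    expect_identical(candidates$bin[idx], sqtls$bin)
    expect_true(all(abs(candidates$maf[idx] - sqtls$maf) <= 0.02 + 1e-12))
  }
  # with replacement across sets: determinism under the seed
  sets2 <- sample_matched_null(sqtls, candidates, spec, seed = 1)
  expect_identical(sets, sets2)

  # candidate pool equal to the sQTL set itself: every set is a permutation
  cand_self <- data.frame(variant_id = sqtls$variant_id, maf = sqtls$maf,
                          bin = sqtls$bin)
  perm_sets <- sample_matched_null(sqtls, cand_self,
                                   matched_null_spec(n_sets = 20), seed = 2)
  for (s in perm_sets) expect_setequal(s, sqtls$variant_id)

  # empty stratum falls back to nearest MAF in-bin; empty bin errors
  far <- data.frame(variant_id = "c1", maf = 0.5, bin = 3L)
  one <- data.frame(variant_id = "s1", maf = 0.05, bin = 3L)
  fb <- sample_matched_null(one, far, matched_null_spec(n_sets = 2), seed = 3)
  expect_identical(attr(fb, "n_fallback"), 1L)
  expect_error(sample_matched_null(one, data.frame(variant_id = "c1",
                                                   maf = 0.5, bin = 9L),
                                   matched_null_spec(n_sets = 2), seed = 3),
               "bin")
})

test_that("enrichment odds ratios match hand arithmetic and the hypergeometric", {
  # 10/100 annotated vs null mean 5/100: OR = (10*95)/(90*5)
  sq <- c(rep(TRUE, 10), rep(FALSE, 90))
  nulls <- rep(5, 1000)
  res <- enrichment_or(list(track = sq), list(track = nulls))
  expect_equal(res$or_value, (10 * 95) / (90 * 5), tolerance = 1e-12)
  expect_equal(res$or_value, 2.111, tolerance = 1e-3)

  # identical rates: OR 1, p 1
  res_eq <- enrichment_or(list(tr = c(rep(TRUE, 5), rep(FALSE, 95))),
                          list(tr = rep(5, 10)))
  expect_equal(res_eq$or_value, 1)
  expect_equal(res_eq$fisher_p, 1)

  # Fisher p equals the exhaustive hypergeometric tail sum for 20/80 vs 5/95
  res2 <- enrichment_or(list(tr = c(rep(TRUE, 20), rep(FALSE, 80))),
                        list(tr = rep(5, 100)))
  m <- matrix(c(20, 80, 5, 95), 2)
  dens <- dhyper(0:25, 25, 175, 100)
  p_oracle <- sum(dens[dens <= dhyper(20, 25, 175, 100) * (1 + 1e-7)])
  expect_equal(res2$fisher_p, p_oracle, tolerance = 1e-9)

  # low-frequency tracks are dropped before FDR
  res3 <- enrichment_or(list(lo = sq, hi = sq),
                        list(lo = rep(2, 10), hi = rep(6, 10)))
  expect_identical(res3$annotation, "hi")
  expect_true("fdr_q" %in% names(res3))
})

test_that("self-drawn null sets calibrate the OR near 1", {
  set.seed(73)
  n <- 200
  ors <- vapply(1:100, function(i) {
    p_tr <- runif(1, 0.1, 0.4)
    annotated <- runif(n) < p_tr
    null_counts <- rbinom(200, n, p_tr)  # null sets drawn from the same law
    enrichment_or(list(tr = annotated), list(tr = null_counts))$or_value
  }, numeric(1))
  expect_gt(mean(ors), 0.9)
  expect_lt(mean(ors), 1.1)
})

test_that("location bins are strand-oriented and profiles average per gene", {
  # offset 150 of 2000 on + strand: bin 2; on - strand: bin 19
  expect_identical(location_bin(150, 0, 2000, "+"), 2L)
  expect_identical(location_bin(150, 0, 2000, "-"), 19L)
  expect_true(is.na(location_bin(2500, 0, 2000, "+")))

  # per-gene proportions sum to 1 and the uniform null is flat
  set.seed(77)
  regions <- data.frame(gene_id = paste0("g", 1:500),
                        start = 0L, end = 2000L, strand = "+")
  sqtls <- data.frame(gene_id = rep(regions$gene_id, each = 4),
                      pos = sample.int(2000, 2000, replace = TRUE) - 1L)
  prof <- location_profile(sqtls, regions)
  expect_equal(sum(prof), 1, tolerance = 1e-12)
  se <- sqrt(0.05 * 0.95 / 4) / sqrt(500)
  expect_true(all(abs(prof - 0.05) < 3 * se + 0.01))

  # the shortest 20% of regions are excluded: their sQTLs (all parked at
  # pos 5, i.e. bin 1 of a 10-bp region) never enter the profile
  regions2 <- regions
  regions2$end[1:100] <- 10L
  sq2 <- rbind(data.frame(gene_id = regions2$gene_id[1:100], pos = 5L),
               data.frame(gene_id = regions2$gene_id[101:500],
                          pos = 1990L))
  prof2 <- location_profile(sq2, regions2)
  expect_equal(prof2[[20]], 1)  # only the long-region sQTLs remain
  expect_equal(prof2[[1]], 0)
})

test_that("heteropleiotropy calls match the brute-force predicate on all 256 inputs", {
  oracle <- function(x) {
    (x[1] & !x[2]) & (x[8] & !x[7]) & (!x[3] & !x[4]) & (!x[5] & !x[6])
  }
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 8))
  names(grid) <- c("sqtl_g1_t1", "eqtl_g1_t1", "sqtl_g2_t1", "eqtl_g2_t1",
                   "sqtl_g1_t2", "eqtl_g1_t2", "sqtl_g2_t2", "eqtl_g2_t2")
  for (i in seq_len(nrow(grid))) {
    calls <- as.logical(grid[i, ])
    names(calls) <- names(grid)
    expect_identical(heteropleiotropy_call(calls),
                     oracle(unname(calls)))
  }
  # missing calls are not evaluable
  calls <- setNames(rep(TRUE, 8), names(grid))
  calls["eqtl_g2_t2"] <- NA
  expect_true(is.na(heteropleiotropy_call(calls)))
})

test_that("PWM delta scoring matches hand log2 arithmetic", {
  uniform <- matrix(0.25, 4, 5, dimnames = list(c("A", "C", "G", "T"), NULL))
  v <- list(offset = 3, ref = "A", alt = "G")
  res <- pwm_delta("AAAAA", v, uniform)
  expect_equal(res$delta, 0)

  one_col <- matrix(c(0.85, 0.05, 0.05, 0.05), 4, 1,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
  r1 <- pwm_delta("A", list(offset = 1, ref = "A", alt = "G"), one_col)
  expect_equal(r1$delta, abs(log2(0.05 / 0.25) - log2(0.85 / 0.25)),
               tolerance = 1e-12)
  expect_equal(r1$delta, 4.087, tolerance = 1e-3)

  # symmetry of the absolute difference
  one_col_g <- one_col
  r2 <- pwm_delta("G", list(offset = 1, ref = "G", alt = "A"), one_col_g)
  expect_equal(r1$delta, r2$delta)

  expect_error(pwm_delta("AAA", list(offset = 9, ref = "A", alt = "G"),
                         matrix(0.25, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))),
               "outside")
  expect_error(pwm_delta("AAA", list(offset = 1, ref = "AT", alt = "A"),
                         matrix(0.25, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))),
               "indel")
})
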