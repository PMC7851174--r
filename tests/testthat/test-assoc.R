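test_that("Hellinger distance matches its closed form and bounds", {
  expect_equal(hellinger_distance(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(hellinger_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(hellinger_distance(c(0.5, 0.5), c(0.98, 0.02)), 0.4472136,
               tolerance = 1e-6)
  expect_error(hellinger_distance(c(0.5, 0.5), c(1, 0, 0)), "length")
  expect_error(hellinger_distance(c(1.2, -0.2), c(0.5, 0.5)), "negative")

  # matrix form: identity with sqrt-Euclidean scaling
  set.seed(1)
  ratios <- matrix(rgamma(30, 3), 10, 3)
  ratios <- ratios / rowSums(ratios)
  d <- hellinger_dist(ratios)
  expect_equal(as.matrix(d), as.matrix(dist(sqrt(ratios)) / sqrt(2)),
               ignore_attr = TRUE)
  expect_true(all(d >= 0 & d <= 1))
})

test_that("pseudo-F agrees across routes and with independent oracles", {
  set.seed(7)
  np <- null_phenotype(30, seed = 7)
  d <- dist(np$Y)
  f_dist <- pseudo_f(d, np$g)
  f_mat <- pseudo_f(np$Y, np$g)
  expect_equal(as.numeric(f_dist), as.numeric(f_mat), tolerance = 1e-10)
  # definitional sums-of-squared-distances oracle
  expect_equal(as.numeric(f_dist), oracle_pseudo_f(d, np$g), tolerance = 1e-10)
  # established PERMANOVA implementation as an independent cross-check
  skip_if_not_installed("vegan")
  ad <- vegan::adonis2(d ~ g, data = data.frame(g = np$g), permutations = 2)
  expect_equal(as.numeric(f_dist), ad$F[1], tolerance = 1e-8)
})

test_that("univariate pseudo-F with Euclidean distance is the ANOVA F", {
  set.seed(8)
  y <- matrix(rnorm(24), 24, 1)
  g <- factor(rep(1:3, each = 8))
  f_classic <- anova(lm(y ~ g))[1, "F value"]
  expect_equal(as.numeric(pseudo_f(dist(y), g)), f_classic, tolerance = 1e-10)
})

test_that("pseudo-F is invariant to consistent sample relabeling and flags degeneracy", {
  np <- null_phenotype(20, seed = 3)
  f0 <- as.numeric(pseudo_f(np$Y, np$g))
  perm <- sample(20)
  f1 <- as.numeric(pseudo_f(np$Y[perm, ], np$g[perm]))
  expect_equal(f0, f1, tolerance = 1e-10)

  flat <- matrix(1, 12, 3)
  fdeg <- pseudo_f(flat, rep(1:2, each = 6))
  expect_true(is.nan(as.numeric(fdeg)))
  expect_true(attr(fdeg, "degenerate"))

  expect_error(pseudo_f(np$Y, rep(1, 20)), "two groups")
})

test_that("exact permutation p-values match exhaustive enumeration", {
  # n=6, 3 vs 3, observed F the largest of all 20 relabelings: p = 1/10
  y <- matrix(c(1, 1.1, 0.9, 5, 5.2, 4.9), 6, 1)
  g <- rep(0:1, each = 3)
  np <- nominal_pvalue(y, g, mode = "exact_perm")
  expect_equal(np$p, 0.1)
  expect_identical(np$n_perms_used, 20L)

  # independent enumeration oracle on random two-group data, n <= 8
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(6:8, 1)
    Y <- matrix(rnorm(2 * n), n, 2)
    g <- rep(0:1, c(floor(n / 2), ceiling(n / 2)))
    expect_equal(nominal_pvalue(Y, g, mode = "exact_perm")$p,
                 oracle_exact_p_2groups(Y, g), tolerance = 1e-12)
  }

  # three-group enumeration: count matches the multinomial coefficient
  y3 <- matrix(rnorm(9), 9, 1)
  g3 <- rep(0:2, each = 3)
  np3 <- nominal_pvalue(y3, g3, mode = "exact_perm")
  expect_identical(np3$n_perms_used, as.integer(factorial(9) / factorial(3)^3))
})

test_that("Monte-Carlo p-values converge to the exact enumeration", {
  set.seed(11)
  Y <- matrix(rnorm(16), 8, 2)
  g <- rep(0:1, each = 4)
  p_exact <- nominal_pvalue(Y, g, mode = "exact_perm")$p
  p_mc <- nominal_pvalue(Y, g, mode = "mc_perm", B = 20000, seed = 2)$p
  expect_lt(abs(p_mc - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 20000) + 1e-4)
  expect_error(nominal_pvalue(Y, g, mode = "mc_perm", B = 10), "B >= 20")
})

test_that("the Pearson-III tail approximation tracks brute-force permutation", {
  # fidelity is claimed for p in [1e-4, 1]; restrict comparisons accordingly
  n_compared <- 0
  for (i in 1:4) {
    gene <- sim_gene(n = 150, effect_md = c(0, 0.04, 0.06, 0.08)[i],
                     seed = 103 + i)
    if (is.null(gene)) next
    g <- factor(gene$dosage)
    pa <- nominal_pvalue(gene$ph$matrix, g, mode = "approx", seed = i)
    pm <- nominal_pvalue(gene$ph$matrix, g, mode = "mc_perm", B = 50000,
                         seed = 100 + i)
    if (pm$p < 1e-4) next
    expect_lt(abs(log10(pa$p) - log10(pm$p)), 0.3)
    n_compared <- n_compared + 1
  }
  expect_gte(n_compared, 2)
})

test_that("p-value machinery is deterministic under a fixed seed", {
  np <- null_phenotype(40, seed = 5)
  p1 <- nominal_pvalue(np$Y, np$g, mode = "mc_perm", B = 200, seed = 42)
  p2 <- nominal_pvalue(np$Y, np$g, mode = "mc_perm", B = 200, seed = 42)
  expect_identical(p1$p, p2$p)
  h1 <- homoscedasticity_test(np$Y, np$g, seed = 7)
  h2 <- homoscedasticity_test(np$Y, np$g, seed = 7)
  expect_identical(h1$p, h2$p)
})

test_that("homoscedasticity screen flags dispersion differences only", {
  # mirror-image groups have identical dispersion: F = 0, p near 1
  set.seed(10)
  half <- matrix(rnorm(30), 15, 2)
  Y <- rbind(half, -half)
  g <- rep(0:1, each = 15)
  h <- homoscedasticity_test(Y, g, seed = 1)
  expect_equal(h$F, 0, tolerance = 1e-12)
  expect_gt(h$p, 0.9)

  # one tight, one spread group at n=200: detected
  set.seed(12)
  Y2 <- rbind(matrix(rnorm(200, sd = 0.2), 100, 2),
              matrix(rnorm(200, sd = 1.5), 100, 2))
  h2 <- homoscedasticity_test(Y2, rep(0:1, each = 100), seed = 1)
  expect_lt(h2$p, 0.01)

  # degenerate dispersion: p = 1 with a flag
  h3 <- homoscedasticity_test(matrix(1, 10, 2), rep(0:1, each = 5), seed = 1)
  expect_identical(h3$p, 1)
  expect_true(h3$degenerate)
})

test_that("homoscedasticity distances match the established dispersion test", {
  skip_if_not_installed("vegan")
  np <- null_phenotype(30, seed = 9)
  bd <- vegan::betadisper(dist(np$Y), np$g, type = "centroid")
  f_ref <- anova(bd)[1, "F value"]
  h <- homoscedasticity_test(np$Y, np$g, seed = 1)
  expect_equal(h$F, f_ref, tolerance = 1e-8)
})

test_that("MD effect size is the max group-mean difference on ratio scale", {
  expect_equal(effect_size_md(rbind(c(0.5, 0.5), c(0.5, 0.5))), 0)
  expect_equal(effect_size_md(rbind(c(1, 0), c(0, 1))), 1)
  expect_equal(effect_size_md(rbind(A = c(0.5, 0.3, 0.2),
                                    B = c(0.3, 0.4, 0.3))), 0.2)
  expect_error(effect_size_md(rbind(c(0.5, 0.5))), "2 groups")

  # with no covariates the adjusted relative expression reconstructs the
  # raw ratios, so group means match raw group means
  gene <- sim_gene(n = 150, effect_md = 0.3, seed = 31)
  gm <- group_adjusted_means(gene$ph$matrix, gene$ph$center,
                             factor(gene$dosage))
  raw <- rowsum(gene$ratios$ratios, gene$dosage) /
    as.integer(table(gene$dosage))
  expect_equal(unname(gm), unname(raw), tolerance = 1e-10)
})

test_that("hellinger on ratios equals scaled Euclidean on sqrt scale (identity)", {
  set.seed(2)
  ratios <- matrix(rgamma(40, 2), 10, 4)
  ratios <- ratios / rowSums(ratios)
  lhs <- as.matrix(hellinger_dist(ratios))
  rhs <- as.matrix(dist(sqrt(ratios))) / sqrt(2)
  expect_equal(lhs, rhs, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("hellinger_permanova returns a printable classed fit", {
  gene <- sim_gene(n = 150, effect_md = 0.3, seed = 41)
  fit <- hellinger_permanova(gene$ph$matrix, gene$dosage, mode = "approx",
                             seed = 1)
  expect_s3_class(fit, "hpermanova")
  expect_lt(fit$p_nominal, 0.01)
  expect_output(print(fit), "pseudo-F")
})
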