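test_that("equal-proportions test reproduces the worked chi-squared values", {
  # counts reconstructed from printed percentages of n = 60 per treatment
  expect_equal(round(equal_proportions_test(10, 60, 20, 60)$statistic, 2), 3.60)
  expect_equal(round(equal_proportions_test(17, 60, 11, 60)$statistic, 2), 1.16)
  expect_equal(round(equal_proportions_test(5, 60, 10, 60)$statistic, 2), 1.22)
  # equal counts: continuity correction floors the statistic at 0
  expect_equal(equal_proportions_test(7, 30, 7, 30)$statistic, 0)
  expect_error(equal_proportions_test(1, 0, 2, 10))
})

test_that("two-sample router picks Welch for normal data, Wilcoxon otherwise", {
  set.seed(61)
  a <- rnorm(60); b <- rnorm(60)
  res <- two_sample_auto(a, b)
  expect_identical(res$test_used, "welch_t")
  heavy <- rcauchy(60); heavy2 <- rcauchy(60)
  res2 <- two_sample_auto(heavy, heavy2)
  expect_identical(res2$test_used, "wilcoxon")
  # identical constant-ish samples: routed to wilcoxon, p = 1
  res3 <- two_sample_auto(rep(1, 10), rep(1, 10))
  expect_identical(res3$test_used, "wilcoxon")
  expect_equal(res3$p_value, 1)
  expect_error(two_sample_auto(1:2, 1:5), "at least 3")
})

test_that("two-sample router holds its nominal size on Gaussian nulls", {
  set.seed(62)
  rej <- mean(replicate(1000, {
    two_sample_auto(rnorm(30), rnorm(30))$p_value < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # order-preserving under input reordering
  p <- c(0.04, 0.001, 0.3, 0.02)
  perm <- c(3, 1, 4, 2)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_true(all(bh_adjust(p) >= p))
})

test_that("Bray-Curtis matches hand examples and flags all-zero pairs", {
  x <- od_vec(0.2, 0.3, fill = 0)
  y <- od_vec(0.1, 0.5, fill = 0)
  d <- bray_curtis(rbind(x, y))
  expect_equal(as.vector(d), 0.3 / 1.1)
  expect_equal(round(as.vector(d), 4), 0.2727)
  expect_equal(as.vector(bray_curtis(rbind(x, x))), 0)
  z <- od_vec(rep(0, 2), 0.4, fill = 0)
  z[3] <- 0.4
  expect_equal(as.vector(bray_curtis(rbind(x, z))), 1)  # disjoint
  zero2 <- rbind(rep(0, 95), rep(0, 95), x)
  dz <- bray_curtis(zero2)
  expect_equal(as.matrix(dz)[1, 2], 1)
  expect_identical(attr(dz, "allzero_pairs"), 1L)
  # invariant to joint rescaling
  expect_equal(as.vector(bray_curtis(rbind(x, y) * 7)), as.vector(d))
})

test_that("PERMANOVA matches the exhaustive-enumeration oracle on 6 samples", {
  set.seed(63)
  x <- matrix(abs(rnorm(6 * 4)), 6, 4)
  rownames(x) <- paste0("s", 1:6)
  d <- vegan::vegdist(x)
  g <- factor(c("a", "a", "a", "b", "b", "b"))
  perms <- all_perms(6)
  res <- permanova_terms(d, data.frame(g = g), ~ g,
                         permutations = perms[-1, , drop = FALSE])
  expect_equal(res$p_value[1], bf_permanova_p(d, g))
  # R2 terms plus residual sum to 1
  expect_equal(sum(res$R2[res$term != "Total"]), 1, tolerance = 1e-9)
  # pseudo-F agrees with the Gower-centering oracle
  expect_equal(res$F[1], bf_pseudo_f(d, g))
})

test_that("PERMANOVA separates planted clusters and is seed-reproducible", {
  set.seed(64)
  x <- rbind(matrix(rnorm(10 * 3, 0), 10, 3), matrix(rnorm(10 * 3, 4), 10, 3))
  d <- dist(x)
  meta <- data.frame(g = rep(c("a", "b"), each = 10))
  r1 <- permanova_terms(d, meta, ~ g, permutations = 199, seed = 7)
  r2 <- permanova_terms(d, meta, ~ g, permutations = 199, seed = 7)
  expect_identical(r1, r2)
  expect_lte(r1$p_value[1], 0.01)
  expect_gt(r1$R2[1], 0.5)
  expect_error(permanova_terms(d, data.frame(g = c("a", rep("b", 19))), ~ g),
               "< 2 samples")
})

test_that("Mantel agrees with exhaustive enumeration and affine invariance", {
  set.seed(65)
  x <- matrix(rnorm(4 * 3), 4, 3)
  d1 <- dist(x)
  d2 <- dist(x + 0.3 * matrix(rnorm(12), 4, 3))
  perms <- all_perms(4)
  res <- mantel_test(d1, d2, permutations = perms[-1, , drop = FALSE])
  expect_equal(res$p_value, bf_mantel_p(d1, d2))
  expect_equal(mantel_test(d1, d1, permutations = 99)$r, 1)
  expect_equal(mantel_test(d1, 2.5 * d1 + 0.3, permutations = 99)$r, 1)
})

test_that("PERMDISP detects a planted dispersion difference; degenerate case flat", {
  set.seed(66)
  base <- matrix(rnorm(15 * 3), 15, 3)
  wide <- matrix(rnorm(15 * 3, sd = 3), 15, 3)
  d <- dist(rbind(base, wide))
  g <- rep(c("tight", "wide"), each = 15)
  res <- dispersion_test(d, g, permutations = 999, seed = 3)
  expect_gt(res$group_means["wide"], res$group_means["tight"])
  expect_lt(res$p_value, 0.05)
  expect_identical(nrow(res$tukey), 1L)
  # identical points: all distances zero
  pts <- matrix(1, 6, 3) + 0  # identical rows
  dz <- dist(pts)
  resz <- dispersion_test(dz, rep(c("a", "b"), 3), permutations = 19)
  expect_equal(unname(resz$distances), rep(0, 6))
})

test_that("permutation p values are reproducible under a fixed seed", {
  set.seed(67)
  x <- matrix(rnorm(12 * 4), 12, 4)
  d <- dist(x)
  g <- rep(c("a", "b"), each = 6)
  p1 <- dispersion_test(d, g, permutations = 99, seed = 11)$p_value
  p2 <- dispersion_test(d, g, permutations = 99, seed = 11)$p_value
  expect_identical(p1, p2)
  m1 <- mantel_test(d, dist(x + 1e-3), permutations = 99, seed = 5)
  m2 <- mantel_test(d, dist(x + 1e-3), permutations = 99, seed = 5)
  expect_identical(m1, m2)
})

test_that("dissimilarity-phylogeny regression recovers planted relations", {
  set.seed(68)
  n <- 40
  x <- matrix(rnorm(n * 5), n, 5)
  rownames(x) <- paste0("i", 1:n)
  d_ph <- dist(x)
  strata <- setNames(rep("all", n), rownames(x))
  # proportional distances: R2 = 1
  res <- suppressWarnings(phylo_pheno_regression(d_ph, 2 * d_ph, strata))
  expect_equal(res$R2, 1)
  # independent distances: R2 near 0 (>= 500 pairs)
  d_ind <- dist(matrix(rnorm(n * 5), n, 5, dimnames = list(rownames(x), NULL)))
  res2 <- phylo_pheno_regression(d_ph, d_ind, strata)
  expect_lt(res2$R2, 0.05)
  expect_gt(res2$n_pairs, 500)
  # planted linear relation with noise: R2 recovered within 0.05
  target_r2 <- 0.3
  d_mix <- simulate_correlated_distance(d_ph, sqrt(target_r2), seed = 2)
  res3 <- phylo_pheno_regression(d_ph, d_mix, strata)
  expect_equal(res3$R2, target_r2, tolerance = 0.05)
  expect_true(isTRUE(attr(res3, "nonindependent_pairs")))
})

test_that("comparison family carries one BH family across its tests", {
  set.seed(69)
  fam <- list(a = list(rnorm(20), rnorm(20)),
              b = list(rnorm(20), rnorm(20, 3)),
              c = list(rnorm(20), rnorm(20)))
  out <- comparison_family(fam)
  expect_identical(out$p_adjusted, bh_adjust(out$p_value))
  expect_true(all(out$p_adjusted >= out$p_value))
})
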