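test_that("theta is exactly 1 for fixed differences and <= 0 for clones", {
  g <- rbind(matrix(0L, 4, 6), matrix(2L, 4, 6))
  res <- wc_fst(g, rep(c("a", "b"), each = 4))
  expect_identical(res$theta, 1)
  expect_identical(res$n_loci_used, 6L)
  # duplicating one group into two identical groups: no among-group variance
  set.seed(5)
  h <- matrix(rbinom(60, 2, 0.4), 10, 6)
  res0 <- wc_fst(rbind(h, h), rep(c("a", "b"), each = 10))
  expect_lte(res0$theta, 0)
})

test_that("theta equals the independent variance-component oracle", {
  g <- fst_toy_table()
  grp <- rep(c("a", "b"), each = 3)
  expect_equal(wc_fst(g, grp)$theta, oracle_wc_fst(g, grp),
               tolerance = 1e-12)
  # and on larger random tables with missing data, up to 8 individuals
  set.seed(11)
  for (i in 1:5) {
    gg <- matrix(sample(c(0:2, NA), 8 * 10, replace = TRUE,
                        prob = c(.3, .3, .3, .1)), 8, 10)
    grp2 <- rep(c("a", "b"), each = 4)
    ok <- tryCatch(wc_fst(gg, grp2)$theta, error = function(e) NULL)
    if (!is.null(ok))
      expect_equal(ok, oracle_wc_fst(gg, grp2), tolerance = 1e-12)
  }
})

test_that("theta is invariant to group label order and allele relabeling", {
  tp <- make_two_pop(n_per = 15, L = 300, seed = 13)
  grp <- tp$metadata$true_group
  g <- tp$genotypes$genotypes
  t1 <- wc_fst(g, grp)$theta
  t2 <- wc_fst(g, factor(grp, levels = rev(unique(grp))))$theta
  expect_equal(t1, t2, tolerance = 1e-12)
  expect_equal(wc_fst(2L - g, grp)$theta, t1, tolerance = 1e-12)
})

test_that("wc_fst rejects degenerate inputs", {
  expect_error(wc_fst(matrix(0L, 4, 2), rep("a", 4)), "2 groups")
  expect_error(wc_fst(matrix(c(0L, 2L, 0L, 2L), 4, 1),
                      c("a", "a", "a", "b")), ">= 2 individuals")
  expect_error(wc_fst(matrix(1L, 4, 0), rep(c("a", "b"), 2)), "loci")
})

test_that("diversity summary matches hand combinatorics and properties", {
  # 2N = 20 gene copies, minor count 3, rarefy to g = 10:
  # AR = 2 - C(17,10)/C(20,10) = 2 - 19448/184756
  g <- matrix(c(rep(0L, 7), 1L, 1L, 1L), 10, 1)
  ds <- diversity_summary(g, rep("x", 10), rarefaction_g = 10)
  expect_equal(ds$AR, 2 - 19448 / 184756, tolerance = 1e-10)
  expect_equal(round(ds$AR, 4), 1.8947)
  # all-heterozygote locus: Ho = 1, FIS < 0
  g2 <- matrix(1L, 8, 1)
  ds2 <- diversity_summary(g2, rep("x", 8), rarefaction_g = 4)
  expect_equal(ds2$Ho, 1)
  expect_lt(ds2$FIS, 0)
  # monomorphic locus contributes exactly 1 allele at any g
  g3 <- cbind(rep(0L, 6), c(0L, 1L, 1L, 0L, 1L, 0L))
  ds3 <- diversity_summary(g3, rep("x", 6), rarefaction_g = 6)
  ar_poly <- (1 - choose(9, 6) / choose(12, 6)) +
    (1 - choose(3, 6) / choose(12, 6))
  expect_equal(ds3$AR, (1 + ar_poly) / 2, tolerance = 1e-10)
  # unbiased He: single locus p = 0.5, n = 4 -> (8/7) * 0.5
  g4 <- matrix(c(0L, 1L, 1L, 2L), 4, 1)
  ds4 <- diversity_summary(g4, rep("x", 4), rarefaction_g = 2)
  expect_equal(ds4$He, (8 / 7) * 0.5, tolerance = 1e-12)
  # rarefaction beyond the smallest 2N errors
  expect_error(diversity_summary(g4, rep("x", 4), rarefaction_g = 9),
               "exceeds")
})

test_that("permutation test is calibrated at its boundaries", {
  # identical groups: p near 1
  set.seed(17)
  h <- matrix(rbinom(200, 2, 0.4), 10, 20)
  g2 <- rbind(h, h)
  res <- differentiation_test(g2, rep(c("a", "b"), each = 10),
                              n_perm = 199, seed = 3)
  expect_gt(res$p_value, 0.5)
  # fixed differences: minimum attainable p = 1/(n_perm + 1), significant.
  # Group sizes of 12 keep the chance of a degenerate relabeling (which
  # would recreate theta = 1) negligible: 2 / choose(24, 12) ~ 7e-7.
  gf <- rbind(matrix(0L, 12, 8), matrix(2L, 12, 8))
  resf <- differentiation_test(gf, rep(c("a", "b"), each = 12),
                               n_perm = 999, alpha = 0.01, seed = 4)
  expect_equal(resf$p_value, 1 / 1000)
  expect_true(resf$significant)
  expect_true(all(resf$theta_perm <= resf$theta_obs))
  expect_warning(
    differentiation_test(gf, rep(c("a", "b"), each = 12), n_perm = 50,
                         seed = 5),
    "coarse")
})
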