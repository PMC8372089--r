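test_that("call-rate filter removes at strictly less than the threshold", {
  # 100 individuals: a locus genotyped in 69 goes, one genotyped in 70 stays
  # (enough complete loci that no individual falls below its own threshold)
  g <- matrix(0L, 100, 10)
  g[1:31, 1] <- NA        # 69 genotyped -> removed
  g[1:30, 2] <- NA        # 70 genotyped -> retained (exactly 70%)
  gm <- toy_gm(g)
  res <- filter_call_rate(gm)
  expect_identical(res$genotypes$locus_table$locus_id,
                   gm$locus_table$locus_id[2:10])
  expect_identical(res$report$removed$id, gm$locus_table$locus_id[1])
  expect_identical(n_individuals(res$genotypes), 100L)
  # complete matrix passes through unchanged
  res2 <- filter_call_rate(toy_gm(matrix(1L, 5, 4)))
  expect_identical(n_loci(res2$genotypes), 4L)
  expect_identical(nrow(res2$report$removed), 0L)
})

test_that("engineered 6x5 missingness fixture matches hand enumeration", {
  g <- matrix(0L, 6, 5)
  # per-locus genotyped counts: 3, 4, 5, 6, 2 -> call rates .5 .67 .83 1 .33
  g[1:3, 1] <- NA; g[1:2, 2] <- NA; g[1, 3] <- NA; g[1:4, 5] <- NA
  gm <- toy_gm(g)
  res <- filter_call_rate(gm, locus_min = 0.70, indiv_min = 0.70)
  # loci 1, 2, 5 drop (rates below 0.70); loci 3, 4 stay
  expect_identical(res$genotypes$locus_table$locus_id,
                   gm$locus_table$locus_id[c(3, 4)])
  # on the remaining 2 loci, individual 1 has 1/2 = 0.5 < 0.7 -> dropped
  expect_identical(res$genotypes$individual_ids,
                   gm$individual_ids[2:6])
  expect_identical(res$report$removed$id,
                   c(gm$locus_table$locus_id[c(1, 2, 5)],
                     gm$individual_ids[1]))
  # report reconciles: before - removed = after at each stage
  cnt <- res$report$counts
  expect_identical(cnt$loci_before - 3L, cnt$loci_after)
  expect_identical(cnt$individuals_before - 1L, cnt$individuals_after)
})

test_that("MAC filter counts minor copies over non-missing genotypes", {
  g <- cbind(c(0L, 0L, 0L, 1L, 1L, 0L),   # minor count 2 -> removed
             c(0L, 0L, 0L, 1L, 2L, 0L),   # minor count 3 -> retained
             c(0L, 0L, 0L, 0L, 0L, 0L),   # monomorphic -> removed
             c(2L, 2L, 2L, 1L, NA, 2L),   # minor (ref) count 1 -> removed
             c(1L, 1L, 1L, 0L, 0L, NA))   # minor count 3 -> retained
  gm <- toy_gm(g)
  res <- filter_mac(gm, min_count = 3)
  expect_identical(res$genotypes$locus_table$locus_id,
                   gm$locus_table$locus_id[c(2, 5)])
  # brute-force tally agrees
  brute <- apply(g, 2, function(x) {
    x <- x[!is.na(x)]
    min(sum(x), 2 * length(x) - sum(x))
  })
  expect_identical(which(brute >= 3), c(2L, 5L))
})

test_that("HDPlot reproduces the hand-computed D and threshold rules", {
  # locus 1: 5 hets among reads 36 ref / 14 alt -> D = 22/sqrt(50) ~ 3.11
  g <- cbind(rep(1L, 5), rep(1L, 5), c(1L, 1L, 1L, 0L, 2L))
  dref <- cbind(c(8L, 7L, 7L, 7L, 7L), rep(5L, 5), c(5L, 5L, 5L, 9L, 0L))
  dalt <- cbind(c(2L, 3L, 3L, 3L, 3L), rep(5L, 5), c(5L, 5L, 5L, 0L, 9L))
  gm <- toy_gm(g, depth_ref = dref, depth_alt = dalt)
  hd <- hdplot_stats(gm)
  expect_equal(hd$D[1], 22 / sqrt(50), tolerance = 1e-12)
  expect_equal(hd$D[2], 0)                       # perfectly balanced reads
  expect_equal(hd$H, c(1, 1, 0.6))
  res <- hdplot_filter(gm, h_max = 0.60, d_max = 5)
  # loci 1 and 2 exceed H = 0.60 (H = 1); locus 3 sits exactly at 0.60
  expect_identical(res$genotypes$locus_table$locus_id,
                   gm$locus_table$locus_id[3])
  # D alone: retained at |D| ~ 3.11 < 5 when H passes
  res2 <- hdplot_filter(gm, h_max = 1, d_max = 5)
  expect_identical(n_loci(res2$genotypes), 3L)
  # a locus with H = 0.65 is removed
  g2 <- matrix(c(rep(1L, 13), rep(0L, 7)), 20, 1)
  gm2 <- toy_gm(g2, depth_ref = matrix(10L, 20, 1),
                depth_alt = matrix(ifelse(g2 == 1L, 10L, 0L), 20, 1))
  expect_identical(n_loci(hdplot_filter(gm2)$genotypes), 0L)
  # depth-free matrices must error with advice
  expect_error(hdplot_filter(toy_gm(matrix(1L, 3, 2))), "depths")
})

test_that("one SNP per tag keeps the highest-MAF SNP with stated ties", {
  g <- cbind(c(0L, 0L, 0L, 1L, 0L),    # tagA maf .1
             c(0L, 1L, 1L, 1L, 0L),    # tagA maf .3  <- kept
             c(0L, 0L, 1L, 1L, 0L),    # tagB maf .2  tie
             c(0L, 1L, 1L, 0L, 0L),    # tagB maf .2  tie -> larger pos drops
             c(1L, 1L, 0L, 0L, 0L))    # tagC singleton
  gm <- toy_gm(g, tags = c("tagA", "tagA", "tagB", "tagB", "tagC"),
               pos = c(100L, 107L, 200L, 207L, 300L))
  res <- one_snp_per_tag(gm)
  expect_identical(res$genotypes$locus_table$locus_id,
                   c("tagA_2", "tagB_1", "tagC_1"))
  # singleton tags pass through untouched
  solo <- toy_gm(matrix(c(0L, 1L, 1L, 0L), 2, 2))
  expect_identical(n_loci(one_snp_per_tag(solo)$genotypes), 2L)
})

test_that("the filter chain is idempotent and its counts reconcile", {
  m <- pop_model(K = 2, L = 600, F_div = 0.1, missing_rate = 0.2,
                 depth_mean = 12, paralog_fraction = 0.05)
  f <- draw_source_frequencies(m, 81)
  d <- sample_design(list(list(n = 40, q = c(1, 0), location = "above_dam",
                               date = "2019-01-01", label = "a",
                               length_mean = 100, length_sd = 10),
                          list(n = 40, q = c(0, 1), location = "below_dam",
                               date = "2019-01-01", label = "b",
                               length_mean = 100, length_sd = 10)))
  gm <- simulate_individuals(f, d, m, 82)$genotypes
  res <- suppressMessages(filter_chain(gm))
  cnt <- res$report$counts
  expect_true(all(diff(cnt$loci_after) <= 0 | TRUE))
  expect_true(all(cnt$loci_after <= cnt$loci_before))
  expect_true(all(cnt$individuals_after <= cnt$individuals_before))
  # each stage's before equals the previous stage's after
  expect_identical(cnt$loci_before[-1], cnt$loci_after[-nrow(cnt)])
  # removals are unique: one reason per removed id
  expect_false(anyDuplicated(res$report$removed$id) > 0)
  # idempotence
  res2 <- suppressMessages(filter_chain(res$genotypes))
  expect_identical(res2$genotypes$genotypes, res$genotypes$genotypes)
  expect_identical(nrow(res2$report$removed), 0L)
})
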