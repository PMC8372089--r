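test_that("Burrows r2 matches a direct hand computation on toy data", {
  set.seed(53)
  g <- cbind(c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 0L, 1L, 2L),
             c(1L, 1L, 2L, 0L, 0L, 2L, 2L, 0L, 1L, 1L),
             c(0L, 0L, 1L, 1L, 2L, 2L, 0L, 1L, 1L, 0L))
  pr <- ld_pairs(g, pcrit = 0.05)
  expect_identical(nrow(pr), 3L)
  for (r in seq_len(nrow(pr))) {
    i <- as.integer(pr$locus1[r]); j <- as.integer(pr$locus2[r])
    expect_equal(pr$r2[r], oracle_burrows_r2(g[, i], g[, j]),
                 tolerance = 1e-12)
  }
  # and with missing entries (pairwise-complete individuals only)
  g2 <- g; g2[c(1, 5), 1] <- NA; g2[2, 3] <- NA
  pr2 <- ld_pairs(g2, pcrit = 0.05)
  r12 <- pr2[pr2$locus1 == "1" & pr2$locus2 == "2", ]
  expect_equal(r12$r2, oracle_burrows_r2(g2[, 1], g2[, 2]),
               tolerance = 1e-12)
  expect_identical(as.integer(r12$n), sum(!is.na(g2[, 1]) & !is.na(g2[, 2])))
})

test_that("pcrit screens loci and the chromosome restriction drops pairs", {
  set.seed(59)
  g <- matrix(rbinom(40 * 4, 2, rep(c(0.5, 0.04, 0.5, 0.5), each = 40)),
              40, 4)
  g[, 2] <- rbinom(40, 2, 0.04)          # MAF ~ 0.04 -> excluded
  while (min(sum(g[, 2]), 80 - sum(g[, 2])) / 80 >= 0.05)
    g[, 2] <- rbinom(40, 2, 0.03)
  pr <- ld_pairs(g, pcrit = 0.05)
  expect_false(any(pr$locus1 == "2" | pr$locus2 == "2"))
  # same-chromosome restriction removes pairs, never adds
  chrom <- c("c1", "c1", "c1", "c2")
  pr_all <- ld_pairs(g, pcrit = 0.05)
  pr_cross <- ld_pairs(g, pcrit = 0.05, chrom = chrom)
  expect_lt(nrow(pr_cross), nrow(pr_all))
  expect_true(all(pr_cross$locus2 == "4"))
  # all loci on one chromosome: no pairs -> error
  expect_error(ld_pairs(g[, 1:3], pcrit = 0.05,
                        chrom = c("c1", "c1", "c1")),
               "cross-chromosome")
})

test_that("the Ne closed form, infinity path and corrections are exact", {
  # r2' = 0.001 -> (1/3 + sqrt(1/9 - 0.00276)) / 0.002
  expect_equal(fragpop:::ne_from_r2prime(0.001),
               (1 / 3 + sqrt(1 / 9 - 2.76 * 0.001)) / 0.002,
               tolerance = 1e-12)
  expect_equal(round(fragpop:::ne_from_r2prime(0.001), 1), 331.3)
  expect_identical(fragpop:::ne_from_r2prime(0), Inf)
  expect_identical(fragpop:::ne_from_r2prime(-0.01), Inf)
  # monotone decreasing in r2' on the finite domain
  r2p <- seq(0.0005, 0.035, length.out = 40)
  ne <- vapply(r2p, fragpop:::ne_from_r2prime, numeric(1))
  expect_true(all(diff(ne) < 0))
  # chromosome-count correction: Ne 100 at Chr = 50 -> ~104.7
  expect_equal(100 / (0.098 + 0.219 * log(50)), 104.7, tolerance = 1e-3)
  pairs <- structure(data.frame(locus1 = "1", locus2 = "2",
                                r2 = 1 / 40 + 3.19 / 1600, n = 40),
                     S = 40, cross_chromosome = FALSE,
                     class = c("ld_pairs", "data.frame"))
  res <- estimate_ne(pairs, n_chromosomes = 50)
  expect_identical(res$correction, "chromosome_count_formula")
  expect_identical(res$ne, Inf)          # r2' = 0 exactly
  expect_error(estimate_ne(pairs, S = 9), "unreliable")
  expect_identical(species_chromosome_counts[["white_sucker"]], 50L)
})

test_that("the estimator recovers Ne from an isolated WF population", {
  g <- simulate_wf_population(100, 3000, generations = 80, seed = 67)
  set.seed(68)
  res <- ld_ne(g[sample.int(100, 50), ], pcrit = 0.05)
  expect_gt(res$ne, 50)
  expect_lt(res$ne, 200)
  expect_true(res$ci[1] <= res$ne && res$ne <= res$ci[2])
})
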