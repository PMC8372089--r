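test_that("source frequency draws are deterministic and honor F_div", {
  m <- pop_model(K = 3, L = 500, F_div = 0.1)
  f1 <- draw_source_frequencies(m, 9)
  f2 <- draw_source_frequencies(m, 9)
  expect_identical(f1, f2)
  expect_true(all(f1 > 0 & f1 < 1))
  # degenerate limit: F_div = 0 copies the ancestral frequencies
  m0 <- pop_model(K = 3, L = 500, F_div = 0)
  f0 <- draw_source_frequencies(m0, 9)
  expect_equal(f0[1, ], attr(f0, "ancestral"), ignore_attr = TRUE)
  expect_equal(f0[2, ], f0[3, ])
})

test_that("realized FST of Balding-Nichols samples tracks F_div", {
  thetas <- vapply(1:5, function(s) {
    tp <- make_two_pop(n_per = 50, L = 2500, F_div = 0.1, seed = 100 + s)
    wc_fst(tp$genotypes, tp$metadata$true_group)$theta
  }, numeric(1))
  expect_true(all(thetas > 0.07 & thetas < 0.13))
})

test_that("realized allele frequencies converge to the specified ones", {
  m <- pop_model(K = 1, L = 300, F_div = 0.05, missing_rate = 0)
  f <- draw_source_frequencies(m, 21)
  d <- sample_design(list(list(n = 2000, q = 1, location = "above_dam",
                               date = "2019-01-01", label = "x",
                               length_mean = 100, length_sd = 10)))
  gm <- simulate_individuals(f, d, m, 22)$genotypes
  dev <- abs(alt_freq(gm) - f[1, ])
  expect_lt(mean(dev), 0.02)
  expect_lt(sqrt(mean(dev^2)), 0.02)
  expect_lt(max(dev), 0.04)      # individual loci within binomial noise
})

test_that("missing_rate 0 yields a complete matrix; MCAR rate is honored", {
  tp <- make_two_pop(n_per = 20, L = 400, seed = 31, missing_rate = 0)
  expect_false(anyNA(tp$genotypes$genotypes))
  tp2 <- make_two_pop(n_per = 40, L = 500, seed = 32, missing_rate = 0.1)
  expect_equal(mean(is.na(tp2$genotypes$genotypes)), 0.1, tolerance = 0.15)
})

test_that("paralog-class loci fail HDPlot while normal loci pass", {
  fails <- vapply(1:3, function(s) {
    m <- pop_model(K = 1, L = 1500, F_div = 0.05, missing_rate = 0,
                   depth_mean = 25, paralog_fraction = 0.05)
    f <- draw_source_frequencies(m, 40 + s)
    d <- sample_design(list(list(n = 60, q = 1, location = "above_dam",
                                 date = "2019-01-01", label = "x",
                                 length_mean = 100, length_sd = 10)))
    gm <- simulate_individuals(f, d, m, 50 + s)$genotypes
    par <- attr(gm, "paralog")
    hd <- hdplot_stats(gm)
    flagged <- hd$H > 0.60 | abs(hd$D) > 5
    c(mean(flagged[par]), mean(flagged[!par]))
  }, numeric(2))
  expect_true(all(fails[1, ] >= 0.90))   # paralogs caught
  expect_true(all(fails[2, ] <= 0.05))   # normal loci mostly retained
})

test_that("parent-offspring spikes satisfy the Mendelian constraint", {
  m <- pop_model(K = 1, L = 800, F_div = 0.05, missing_rate = 0)
  f <- draw_source_frequencies(m, 61)
  gm0 <- toy_gm(matrix(rbinom(2 * 800, 2, rep(f[1, ], each = 2)), 2, 800))
  sp <- spike_relatives(gm0, f, data.frame(relationship = "parent_offspring",
                                           pop = 1, count = 5), seed = 62)
  expect_identical(n_individuals(sp$genotypes), 12L)
  for (r in seq_len(nrow(sp$pairs))) {
    pg <- sp$genotypes$genotypes[sp$pairs$id1[r], ]
    cg <- sp$genotypes$genotypes[sp$pairs$id2[r], ]
    # a homozygous parent always transmits that allele
    expect_true(all(cg[pg == 0L] <= 1L))
    expect_true(all(cg[pg == 2L] >= 1L))
  }
  # zero pairs requested leaves the matrix unchanged
  none <- spike_relatives(gm0, f, data.frame(relationship = character(0),
                                             pop = integer(0),
                                             count = integer(0)), seed = 63)
  expect_identical(none$genotypes$genotypes, gm0$genotypes)
  expect_error(
    spike_relatives(gm0, f, data.frame(relationship = "cousin", pop = 1,
                                       count = 1), seed = 64),
    "unknown relationship")
})

test_that("empty designs give empty outputs", {
  m <- pop_model(K = 1, L = 50, F_div = 0.1)
  f <- draw_source_frequencies(m, 70)
  d <- sample_design(list(list(n = 0, q = 1, location = "above_dam",
                               date = "2019-01-01", label = "x",
                               length_mean = 100, length_sd = 10)))
  s <- simulate_individuals(f, d, m, 71)
  expect_identical(n_individuals(s$genotypes), 0L)
  expect_identical(nrow(s$metadata), 0L)
})
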