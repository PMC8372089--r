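test_that("the estimator is symmetric and invariant to allele relabeling", {
  set.seed(71)
  g <- matrix(rbinom(20 * 400, 2, rep(runif(400, 0.2, 0.8), each = 20)),
              20, 400)
  r1 <- wang_relatedness(g)$estimates
  expect_equal(r1, t(r1))
  expect_true(all(is.na(diag(r1))))
  r2 <- wang_relatedness(2L - g)$estimates
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("clones, relatives and unrelated pairs are calibrated", {
  set.seed(73)
  L <- 1200
  p <- runif(L, 0.15, 0.85)
  n_unrel <- 40
  g <- matrix(rbinom(n_unrel * L, 2, rep(p, each = n_unrel)), n_unrel, L)
  # clone pair: duplicate an individual
  g <- rbind(g, g[1, ])
  r <- wang_relatedness(g, freq_source = p)
  clone_r <- r$estimates[1, nrow(g)]
  expect_gte(clone_r, 0.9)
  unrel <- r$estimates[2:n_unrel, 2:n_unrel]
  expect_lt(abs(mean(unrel[upper.tri(unrel)])), 0.05)
})

test_that("pedigree expectation ordering holds on simulated pairs", {
  set.seed(79)
  L <- 1000
  p <- runif(L, 0.2, 0.8)
  draw <- function(n) matrix(rbinom(n * L, 2, rep(p, each = n)), n, L)
  gam <- function(g) rbinom(L, 1, g / 2)
  n_pairs <- 50
  ms <- vapply(seq_len(n_pairs), function(i) {
    pa <- draw(1)[1, ]; pb <- draw(1)[1, ]; pc <- draw(1)[1, ]
    fs1 <- gam(pa) + gam(pb); fs2 <- gam(pa) + gam(pb)   # full sibs
    hs1 <- gam(pa) + gam(pc); hs2 <- gam(pa) + rbinom(L, 1, p) # half sibs
    po_child <- gam(pa) + rbinom(L, 1, p)                # parent-offspring
    ur1 <- draw(1)[1, ]; ur2 <- draw(1)[1, ]
    gg <- rbind(fs1, fs2, hs1, hs2, pa, po_child, ur1, ur2)
    est <- wang_relatedness(gg, freq_source = p)$estimates
    c(fs = est[1, 2], hs = est[3, 4], po = est[5, 6], ur = est[7, 8])
  }, numeric(4))
  means <- rowMeans(ms)
  expect_equal(unname(means["fs"]), 0.5, tolerance = 0.05)
  expect_equal(unname(means["po"]), 0.5, tolerance = 0.05)
  expect_equal(unname(means["hs"]), 0.25, tolerance = 0.05)
  expect_equal(unname(means["ur"]), 0, tolerance = 0.05)
  expect_gt(means["fs"], means["hs"])
  expect_gt(means["hs"], means["ur"])
})

test_that("related-pair flagging is strict at the threshold", {
  est <- matrix(NA_real_, 4, 4,
                dimnames = list(paste0("i", 1:4), paste0("i", 1:4)))
  est[1, 2] <- est[2, 1] <- 0.45
  est[1, 3] <- est[3, 1] <- 0.40       # exactly at the threshold: not flagged
  est[2, 3] <- est[3, 2] <- 0.10
  est[1, 4] <- est[4, 1] <- 0.41
  est[2, 4] <- est[4, 2] <- -0.1
  est[3, 4] <- est[4, 3] <- 0.2
  nl <- matrix(500L, 4, 4, dimnames = dimnames(est))
  rm_ <- structure(list(estimates = est, n_loci = nl),
                   class = "relatedness_matrix")
  md <- data.frame(individual_id = paste0("i", 1:4),
                   location = c("above_dam", "above_dam", "below_dam",
                                "below_dam"))
  pairs <- find_related_pairs(rm_, 0.4, metadata = md,
                              groups = c(i1 = "BR", i2 = "BR", i3 = "GL",
                                         i4 = "BR"))
  expect_identical(nrow(pairs), 2L)
  expect_identical(pairs$id1, c("i1", "i1"))
  expect_identical(pairs$id2, c("i2", "i4"))
  expect_identical(pairs$location1, c("above_dam", "above_dam"))
  expect_identical(pairs$group2, c("BR", "BR"))
  # empty matrix gives an empty list
  empty <- structure(list(estimates = est * NA, n_loci = nl),
                     class = "relatedness_matrix")
  expect_identical(nrow(find_related_pairs(empty)), 0L)
})

test_that("pairs sharing no genotyped loci yield NA with a warning", {
  g <- rbind(c(0L, 1L, NA, NA), c(NA, NA, 1L, 2L), c(0L, 1L, 1L, 2L),
             c(1L, 1L, 0L, 2L))
  expect_warning(r <- wang_relatedness(g), "no informative")
  expect_true(is.na(r$estimates[1, 2]))
})
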