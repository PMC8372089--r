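test_that("PCA satisfies its structural properties", {
  tp <- make_two_pop(n_per = 12, L = 300, seed = 19, missing_rate = 0.05)
  g <- tp$genotypes$genotypes
  # duplicated individuals get identical scores
  g2 <- rbind(g, g[3, , drop = FALSE])
  pc <- pca_genotypes(g2, n_components = 4)
  expect_equal(pc$scores[3, ], pc$scores[nrow(g2), ], tolerance = 1e-8)
  expect_true(all(diff(pc$variance_explained) <= 1e-12))
  expect_lte(sum(pc$variance_explained), 1 + 1e-12)
  # all-missing loci are dropped with a warning
  g3 <- cbind(g, NA_integer_)
  expect_warning(pca_genotypes(g3, 2), "all-missing")
})

test_that("PCA separates two diverged populations on PC1", {
  tp <- make_two_pop(n_per = 50, L = 2000, F_div = 0.2, seed = 23)
  pc <- pca_genotypes(tp$genotypes, n_components = 2)
  grp <- tp$metadata$true_group
  m1 <- mean(pc$scores[grp == "p1", 1])
  m2 <- mean(pc$scores[grp == "p2", 1])
  pooled_sd <- sqrt(mean(c(var(pc$scores[grp == "p1", 1]),
                           var(pc$scores[grp == "p2", 1]))))
  expect_gt(abs(m1 - m2) / pooled_sd, 4)
})

test_that("K = 1 admixture fit is the closed-form MLE", {
  tp <- make_two_pop(n_per = 10, L = 200, seed = 29, missing_rate = 0.1)
  g <- tp$genotypes$genotypes
  fit <- fit_admixture(g, 1)
  expect_true(all(fit$Q == 1))
  p_obs <- colSums(g, na.rm = TRUE) / (2 * colSums(!is.na(g)))
  expect_equal(as.numeric(fit$F),
               unname(pmin(pmax(p_obs, 1e-6), 1 - 1e-6)),
               tolerance = 1e-12)
})

test_that("EM log-likelihood is non-decreasing and recovery is accurate", {
  tp <- make_two_pop(n_per = 30, L = 600, F_div = 0.15, seed = 37,
                     missing_rate = 0.05)
  fit <- fit_admixture(tp$genotypes, 2, n_restarts = 2, max_iter = 600,
                       tol = 1e-4, seed = 5)
  expect_true(all(diff(fit$ll_trace) >= -1e-8))
  fit <- align_components(fit, tp$freqs)
  truth <- rbind(matrix(c(1, 0), 30, 2, byrow = TRUE),
                 matrix(c(0, 1), 30, 2, byrow = TRUE))
  expect_lt(mean(abs(fit$Q - truth)), 0.06)
  # frequency recovery after alignment
  expect_lt(mean(abs(fit$F - tp$freqs)), 0.05)
})

test_that("cross-validation prefers the generating K", {
  # single population: K = 1 wins
  m <- pop_model(K = 1, L = 400, F_div = 0.05, missing_rate = 0)
  f <- draw_source_frequencies(m, 41)
  d <- sample_design(list(list(n = 40, q = 1, location = "above_dam",
                               date = "2019-01-01", label = "x",
                               length_mean = 100, length_sd = 10)))
  gm <- simulate_individuals(f, d, m, 42)$genotypes
  ks1 <- select_K(gm, 1:3, folds = 4, seed = 2, n_restarts = 1,
                  tol = 0.5, max_iter = 60)
  expect_identical(ks1$best_K, 1L)
  # two populations at F_div = 0.15: K = 2 wins
  tp <- make_two_pop(n_per = 30, L = 600, F_div = 0.15, seed = 43)
  ks2 <- select_K(tp$genotypes, 1:3, folds = 4, seed = 2, n_restarts = 1,
                  tol = 0.5, max_iter = 60)
  expect_identical(ks2$best_K, 2L)
  expect_error(select_K(tp$genotypes, 1:2, folds = 1), "folds")
})

test_that("group assignment applies the Q-score rules", {
  Q <- rbind(c(0.95, 0.05), c(0.65, 0.35), c(0.50, 0.50), c(0.20, 0.80),
             c(0.70, 0.30))
  rownames(Q) <- paste0("i", 1:5)
  asg <- assign_groups(Q, admix_cutoff = 0.7)
  a <- asg$assignments
  expect_identical(a$group, c("group1", "group1", "group1", "group2",
                              "group1"))
  # admixed iff max Q < 0.7: 0.65 and the 0.5 tie flag; 0.70 exactly does not
  expect_identical(a$admixed, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  # threshold monotonicity: raising the cutoff never unflags
  asg2 <- assign_groups(Q, admix_cutoff = 0.8)
  expect_true(all(a$admixed <= asg2$assignments$admixed))
  # idempotence on the same input
  expect_identical(assign_groups(Q)$assignments, asg$assignments)
  # per-location proportions
  md <- data.frame(individual_id = paste0("i", 1:5),
                   location = c("above_dam", "above_dam", "below_dam",
                                "below_dam", "below_dam"))
  asg3 <- assign_groups(Q, metadata = md)
  bl <- asg3$by_location
  expect_equal(bl$prop_admixed[bl$location == "above_dam"], 0.5)
  expect_equal(bl$prop_admixed[bl$location == "below_dam"], 1 / 3)
  expect_error(assign_groups(matrix(c(0.5, 0.4), 1, 2)), "sum to 1")
})

test_that("component alignment undoes label switching", {
  F_ref <- matrix(runif(2 * 100, 0.1, 0.9), 2, 100)
  fit <- structure(list(Q = cbind(rep(0.2, 5), rep(0.8, 5)),
                        F = F_ref[2:1, ], K = 2),
                   class = "ancestry_result")
  al <- align_components(fit, F_ref)
  expect_equal(al$perm, c(2, 1), ignore_attr = TRUE)
  expect_equal(al$F, F_ref)
  expect_equal(al$Q[1, ], c(0.8, 0.2))
})
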