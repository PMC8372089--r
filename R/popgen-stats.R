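## Per-group per-locus summaries used by the Weir-Cockerham estimator.
## Returns matrices (groups x loci) of genotyped counts, alt frequencies and
## observed heterozygote proportions, computed with missing genotypes
## excluded locus-by-locus.
group_locus_summaries <- function(g, groups) {
  groups <- factor(groups)
  obs <- !is.na(g)
  g0 <- g; g0[!obs] <- 0L
  n_gl <- rowsum(obs + 0L, groups)               # genotyped per group/locus
  alt <- rowsum(g0, groups)
  het <- rowsum((g == 1L & obs) + 0L, groups)
  p <- ifelse(n_gl > 0, alt / (2 * n_gl), NA_real_)
  h <- ifelse(n_gl > 0, het / n_gl, NA_real_)
  list(groups = groups, n = n_gl, p = p, h = h)
}

#' Weir-Cockerham FST (theta)
#'
#' The variance-components estimator of FST for biallelic loci: per locus the
#' allele-frequency variance is partitioned into components a (among
#' populations), b (among individuals within populations) and c (within
#' individuals), and the multi-locus estimate is the ratio of sums,
#' theta = sum(a) / sum(a + b + c). Missing genotypes are excluded per locus;
#' loci monomorphic across all groups, or genotyped in fewer than one
#' individual in any group, are excluded from the sums.
#'
#' @param gm a `genotype_matrix` or plain dosage matrix (individuals x loci).
#' @param groups group labels, one per individual; at least two groups with
#'   at least two genotyped individuals each.
#' @return object of class `fst_result`: list with `theta` (multi-locus),
#'   `per_locus` (data.frame of a, b, c, theta per retained locus) and
#'   `n_loci_used`.
#' @export
wc_fst <- function(gm, groups) {
  g <- if (inherits(gm, "genotype_matrix")) gm$genotypes else as.matrix(gm)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (length(groups) != nrow(g)) stop("groups must match individuals")
  grp_n <- table(groups)
  if (any(grp_n < 2)) stop("every group needs >= 2 individuals")
  s <- group_locus_summaries(g, groups)
  r <- nlevels(groups)

  usable <- colSums(s$n >= 1) == r               # every group represented
  n <- s$n[, usable, drop = FALSE]
  p <- s$p[, usable, drop = FALSE]
  h <- s$h[, usable, drop = FALSE]

  nbar <- colMeans(n)
  nc <- (r * nbar - colSums(n^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(n * p) / (r * nbar)
  s2 <- colSums(n * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(n * h) / (r * nbar)

  poly <- pbar > 0 & pbar < 1 & nbar > 1 & nc > 0
  if (!any(poly)) stop("no usable polymorphic loci")
  nbar <- nbar[poly]; nc <- nc[poly]; pbar <- pbar[poly]
  s2 <- s2[poly]; hbar <- hbar[poly]

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  denom <- a + b + cc
  theta <- sum(a) / sum(denom)
  per_locus <- data.frame(
    locus_id = (if (inherits(gm, "genotype_matrix"))
      gm$locus_table$locus_id[usable][poly] else
        which(usable)[poly]),
    a = a, b = b, c = cc,
    theta = ifelse(denom != 0, a / denom, NA_real_))
  structure(list(theta = theta, per_locus = per_locus,
                 n_loci_used = sum(poly)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("Weir-Cockerham multi-locus theta =", signif(x$theta, 4),
      "over", x$n_loci_used, "loci\n")
  invisible(x)
}

## log choose(n, k), with choose(n, k) = 0 for n < k
lchoose0 <- function(n, k) ifelse(n >= k, lchoose(n, k), -Inf)

#' Per-group diversity summary
#'
#' For each group: observed heterozygosity Ho (mean over loci of the
#' heterozygote proportion), unbiased expected heterozygosity He with the
#' small-sample 2n/(2n-1) correction, rarefied allelic richness AR (expected
#' number of distinct alleles in a standardized subsample of `rarefaction_g`
#' gene copies, averaged over loci; between 1 and 2 for biallelic data), and
#' the inbreeding coefficient FIS = 1 - mean(Ho_l)/mean(He_l) (ratio of
#' means across loci, which is stable at low-diversity loci).
#'
#' @param gm a `genotype_matrix` or dosage matrix.
#' @param groups group labels, one per individual.
#' @param rarefaction_g gene copies to rarefy to; the default is 2 x the
#'   smallest group size, capped at the smallest per-locus genotyped 2N so
#'   that missing genotypes cannot push a locus below the rarefaction depth.
#'   An explicitly supplied g exceeding the smallest genotyped 2N errors.
#' @return data.frame, one row per group: `group`, `n`, `Ho`, `He`, `AR`,
#'   `FIS`.
#' @export
diversity_summary <- function(gm, groups, rarefaction_g = NULL) {
  g <- if (inherits(gm, "genotype_matrix")) gm$genotypes else as.matrix(gm)
  groups <- factor(groups)
  if (any(table(groups) == 0)) stop("empty group")
  gsizes <- table(groups)
  g_raref <- rarefaction_g %||% {
    n_gl <- rowsum((!is.na(g)) + 0L, groups)
    min(2 * min(gsizes), 2 * min(n_gl[n_gl > 0]))
  }
  out <- lapply(levels(groups), function(lv) {
    sub <- g[groups == lv, , drop = FALSE]
    obs <- !is.na(sub)
    n_l <- colSums(obs)
    use <- n_l > 0
    sub <- sub[, use, drop = FALSE]; n_l <- n_l[use]
    alt <- colSums(sub, na.rm = TRUE)
    p <- alt / (2 * n_l)
    ho_l <- colSums(sub == 1L, na.rm = TRUE) / n_l
    he_l <- (2 * n_l / (2 * n_l - 1)) * 2 * p * (1 - p)
    if (any(2 * n_l < g_raref))
      stop("rarefaction g = ", g_raref, " exceeds the smallest genotyped 2N (",
           min(2 * n_l), ") in group ", lv)
    c_alt <- alt; c_ref <- 2 * n_l - alt
    ar_l <- (1 - exp(lchoose0(2 * n_l - c_alt, g_raref) -
                       lchoose(2 * n_l, g_raref))) +
            (1 - exp(lchoose0(2 * n_l - c_ref, g_raref) -
                       lchoose(2 * n_l, g_raref)))
    data.frame(group = lv, n = sum(groups == lv),
               Ho = mean(ho_l), He = mean(he_l), AR = mean(ar_l),
               FIS = 1 - mean(ho_l) / mean(he_l))
  })
  do.call(rbind, out)
}

#' Permutation test for genetic differentiation
#'
#' Tests H0: no differentiation between two groups by permuting individuals
#' across groups (preserving group sizes) and recomputing the multi-locus
#' Weir-Cockerham theta. The p-value uses the add-one rule
#' p = (1 + #\{theta_perm >= theta_obs\}) / (n_perm + 1), so the smallest
#' attainable p is 1/(n_perm + 1) and the test is exact by construction.
#'
#' @param gm a `genotype_matrix` or dosage matrix.
#' @param groups two-level group labels.
#' @param n_perm number of permutations (warning below 99).
#' @param alpha significance level recorded in the result (default 0.01).
#' @param seed integer seed for the permutations.
#' @return list with `p_value`, `theta_obs`, `theta_perm`, `n_perm`,
#'   `alpha`, `significant`.
#' @export
differentiation_test <- function(gm, groups, n_perm = 1000, alpha = 0.01,
                                 seed = 1) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("differentiation test expects two groups")
  if (n_perm < 99) warning("n_perm < 99 gives a coarse p-value")
  g <- if (inherits(gm, "genotype_matrix")) gm$genotypes else as.matrix(gm)
  theta_obs <- wc_fst(g, groups)$theta
  set.seed(seed)
  theta_perm <- vapply(seq_len(n_perm), function(i) {
    wc_fst(g, sample(groups))$theta
  }, numeric(1))
  p <- (1 + sum(theta_perm >= theta_obs)) / (n_perm + 1)
  list(p_value = p, theta_obs = theta_obs, theta_perm = theta_perm,
       n_perm = n_perm, alpha = alpha, significant = p <= alpha)
}
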