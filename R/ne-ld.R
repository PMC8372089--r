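#' Default chromosome counts for the study species without genome assemblies
#'
#' Haploid chromosome numbers used by the chromosome-count bias correction
#' when no genome assembly is available to restrict locus pairs to different
#' chromosomes: 23 for smallmouth bass, 24 for rock bass, 50 for white
#' sucker.
#'
#' @format named integer vector.
#' @export
species_chromosome_counts <- c(smallmouth_bass = 23L, rock_bass = 24L,
                               white_sucker = 50L)

#' Pairwise composite-LD r-squared table
#'
#' Computes Burrows' composite disequilibrium between every retained locus
#' pair from unphased dosages: Delta = cov(X, Y) / 2 over pairwise-complete
#' individuals (sample covariance, n - 1 denominator), and
#' r2 = Delta^2 / (pA (1 - pA) pB (1 - pB)) with pair-specific allele
#' frequencies. Loci whose within-group minor allele frequency is below
#' `pcrit` are excluded first; when a chromosome map is available, only
#' pairs on different chromosomes are retained (physical linkage would
#' otherwise bias the LD signal upward and Ne downward).
#'
#' @param gm a `genotype_matrix` or dosage matrix.
#' @param group optional logical/integer index of individuals forming the
#'   population; default all.
#' @param pcrit minor-allele-frequency screening threshold (default 0.05);
#'   loci with MAF < pcrit are excluded.
#' @param chrom optional per-locus chromosome labels (taken from the
#'   `genotype_matrix` locus table when `TRUE`); when given, only
#'   cross-chromosome pairs are kept.
#' @param min_pair_n minimum pairwise-complete individuals for a pair.
#' @return object of class `ld_pairs`: data.frame with `locus1`, `locus2`,
#'   `r2`, `n`; attributes `S` (harmonic mean pair sample size) and
#'   `cross_chromosome` (whether the restriction was applied).
#' @export
ld_pairs <- function(gm, group = NULL, pcrit = 0.05, chrom = NULL,
                     min_pair_n = 2) {
  core <- ld_pairs_core(gm, group, pcrit, chrom, min_pair_n)
  out <- data.frame(locus1 = core$loci_names[core$ai],
                    locus2 = core$loci_names[core$bi],
                    r2 = core$r2, n = core$n,
                    stringsAsFactors = FALSE)
  attr(out, "S") <- 1 / mean(1 / core$n)
  attr(out, "cross_chromosome") <- core$cross
  class(out) <- c("ld_pairs", "data.frame")
  out
}

## Shared pair-level computation. Everything stays in flat vectors so the
## full-scale case (millions of pairs) never materializes per-pair strings.
ld_pairs_core <- function(gm, group, pcrit, chrom, min_pair_n) {
  g <- if (inherits(gm, "genotype_matrix")) gm$genotypes else as.matrix(gm)
  chrom_labels <- NULL
  if (isTRUE(chrom)) {
    if (!inherits(gm, "genotype_matrix"))
      stop("chrom = TRUE needs a genotype_matrix")
    chrom_labels <- gm$locus_table$chrom
  } else if (!is.null(chrom) && !isFALSE(chrom)) {
    chrom_labels <- chrom
  }
  if (!is.null(group)) g <- g[group, , drop = FALSE]
  storage.mode(g) <- "double"

  loci_names <- colnames(g) %||% as.character(seq_len(ncol(g)))
  p <- colSums(g, na.rm = TRUE) / (2 * colSums(!is.na(g)))
  keep <- !is.na(p) & pmin(p, 1 - p) >= pcrit
  if (sum(keep) < 2)
    stop("fewer than 2 loci pass pcrit = ", pcrit)
  g <- g[, keep, drop = FALSE]
  loci_names <- loci_names[keep]
  if (!is.null(chrom_labels)) chrom_labels <- chrom_labels[keep]
  L <- ncol(g)

  anyna <- anyNA(g)
  if (anyna) {
    M <- (!is.na(g)) + 0
    G0 <- g; G0[is.na(g)] <- 0
    N <- crossprod(M)                  # pairwise-complete counts
    SX <- crossprod(G0, M)             # SX[a,b] = sum of x_a over complete
  } else {
    n_all <- nrow(g)
    G0 <- g
    N <- matrix(n_all, L, L)
    SX <- matrix(colSums(g), L, L, byrow = FALSE)  # sums identical per pair
  }
  SXY <- crossprod(G0)                 # sum x*y over complete pairs

  ut <- which(upper.tri(N))
  ai_all <- (ut - 1L) %% L + 1L              # row index (column-major)
  bi_all <- (ut - 1L) %/% L + 1L             # column index
  n_ab <- N[ut]
  ok <- n_ab >= max(2, min_pair_n)
  SXu <- SX[ut]
  SYu <- t(SX)[ut]
  cov_ab <- (SXY[ut] - SXu * SYu / n_ab) / (n_ab - 1)
  pA <- SXu / (2 * n_ab)
  pB <- SYu / (2 * n_ab)
  denom <- pA * (1 - pA) * pB * (1 - pB)
  ok <- ok & denom > 0
  if (!is.null(chrom_labels)) {
    ok <- ok & chrom_labels[ai_all] != chrom_labels[bi_all]
  }
  if (!any(ok)) stop("no usable locus pairs",
                     if (!is.null(chrom_labels))
                       " (cross-chromosome restriction removed all pairs)")
  list(ai = ai_all[ok], bi = bi_all[ok],
       r2 = (cov_ab[ok] / 2)^2 / denom[ok], n = n_ab[ok],
       loci_names = loci_names, cross = !is.null(chrom_labels))
}

## weighted mean r2 / S / pair count without building the pair table.
## For complete matrices with no chromosome restriction the mean reduces to
## a quadratic form: sum_{a<b} r2_ab = (u' (C o C) u - sum_a u_a^2 C_aa^2)/8
## with C the dosage covariance and u_a = 1/(p_a(1-p_a)), which needs only
## a couple of passes over one L x L matrix instead of 3 L^2/2 pair records.
ld_r2_summary <- function(gm, group = NULL, pcrit = 0.05, chrom = NULL,
                          min_pair_n = 2) {
  g <- if (inherits(gm, "genotype_matrix")) gm$genotypes else as.matrix(gm)
  if (is.null(chrom) && !anyNA(if (is.null(group)) g else
                               g[group, , drop = FALSE])) {
    if (!is.null(group)) g <- g[group, , drop = FALSE]
    storage.mode(g) <- "double"
    n <- nrow(g)
    p <- colMeans(g) / 2
    keep <- pmin(p, 1 - p) >= pcrit
    if (sum(keep) < 2) stop("fewer than 2 loci pass pcrit = ", pcrit)
    g <- g[, keep, drop = FALSE]
    p <- p[keep]
    L <- ncol(g)
    C <- crossprod(g - rep(1, n) %o% (2 * p)) / (n - 1)
    u <- 1 / (p * (1 - p))
    M1 <- C * C          # elementwise square
    M1 <- M1 * u         # row-scale: u_a * C_ab^2
    total <- sum(.colSums(M1, L, L) * u)
    diag_term <- sum(u^2 * diag(C)^2)
    n_pairs <- L * (L - 1) / 2
    return(list(r2_mean = (total - diag_term) / 8 / n_pairs, S = n,
                n_pairs = n_pairs, cross = FALSE))
  }
  core <- ld_pairs_core(gm, group, pcrit, chrom, min_pair_n)
  list(r2_mean = sum(core$r2 * core$n) / sum(core$n),
       S = 1 / mean(1 / core$n), n_pairs = length(core$r2),
       cross = core$cross)
}

## exact inverse of ne_from_r2prime on its finite domain:
## Ne = (1/3 + sqrt(1/9 - 2.76 r)) / (2r)  <=>  r = 1/(3 Ne) - 0.69/Ne^2
inverse_ne_r2prime <- function(ne) 1 / (3 * ne) - 0.69 / ne^2

ne_from_r2prime <- function(r2p) {
  if (!is.finite(r2p) || r2p <= 0) return(Inf)
  disc <- 1 / 9 - 2.76 * r2p
  if (disc < 0) return(Inf)
  (1 / 3 + sqrt(disc)) / (2 * r2p)
}

#' LD-based effective population size
#'
#' The bias-corrected linkage-disequilibrium estimator for a random-mating
#' population. The weighted mean pair r2 (weights = pairwise sample size) is
#' reduced by the sampling expectation E[r2 | S] = 1/S + 3.19/S^2 (random
#' mating, S >= 30), giving the drift signal r2'; the point estimate is
#' Ne = (1/3 + sqrt(1/9 - 2.76 r2')) / (2 r2'). Non-positive r2' (sampling
#' noise swamps drift) yields Ne = +Inf, as does a negative discriminant.
#' When the pair table was not restricted to cross-chromosome pairs and a
#' chromosome count is supplied, the physical-linkage bias is corrected by
#' dividing Ne by (0.098 + 0.219 ln Chr). Confidence intervals are
#' parametric chi-square on the number of locus pairs.
#'
#' @param pairs an [ld_pairs()] table.
#' @param S sample size (harmonic mean over pairs by default); must be
#'   >= 10, below which the estimator is unreliable.
#' @param n_chromosomes optional haploid chromosome count for the bias
#'   correction (ignored when the pair table is already cross-chromosome).
#' @param ci_method `"parametric"` (chi-square on the pair count).
#' @param alpha 1 - confidence level (default 0.05, a 95% CI).
#' @return object of class `ne_result`: `r2_mean`, `expected_r2`,
#'   `r2_prime`, `S`, `n_pairs`, `ne` (finite or +Inf), `ci` (low, high),
#'   `correction`.
#' @export
estimate_ne <- function(pairs, S = NULL, n_chromosomes = NULL,
                        ci_method = "parametric", alpha = 0.05) {
  if (is.list(pairs) && !is.data.frame(pairs) &&
      !is.null(pairs$r2_mean)) {               # ld_r2_summary() result
    S <- S %||% pairs$S
    r2m <- pairs$r2_mean
    npairs <- pairs$n_pairs
    cross <- isTRUE(pairs$cross)
  } else {
    S <- S %||% attr(pairs, "S")
    r2m <- wmean(pairs$r2, pairs$n)
    npairs <- nrow(pairs)
    cross <- isTRUE(attr(pairs, "cross_chromosome"))
  }
  if (is.null(S)) stop("supply S or use an ld_pairs table")
  if (S < 10) stop("S = ", round(S, 1), " < 10: estimator unreliable")
  E <- 1 / S + 3.19 / S^2
  r2p <- r2m - E
  ne <- ne_from_r2prime(r2p)

  corr_factor <- 1
  correction <- if (cross) "cross_chromosome_pairs" else "none"
  if (!cross && !is.null(n_chromosomes)) {
    corr_factor <- 0.098 + 0.219 * log(n_chromosomes)
    correction <- "chromosome_count_formula"
  }

  ci <- c(NA_real_, NA_real_)
  if (identical(ci_method, "parametric") && npairs >= 2) {
    r2_lo <- r2m * npairs / stats::qchisq(1 - alpha / 2, npairs)
    r2_hi <- r2m * npairs / stats::qchisq(alpha / 2, npairs)
    ci <- c(ne_from_r2prime(r2_hi - E), ne_from_r2prime(r2_lo - E))
  }
  structure(list(r2_mean = r2m, expected_r2 = E, r2_prime = r2p, S = S,
                 n_pairs = npairs, ne = ne / corr_factor,
                 ci = ci / corr_factor, correction = correction,
                 n_chromosomes = if (correction == "chromosome_count_formula")
                   n_chromosomes),
            class = "ne_result")
}

#' @export
print.ne_result <- function(x, ...) {
  fmt <- function(v) ifelse(is.finite(v), sprintf("%.1f", v), "Inf")
  cat("LD Ne = ", fmt(x$ne), "  (", fmt(x$ci[1]), " - ", fmt(x$ci[2]),
      "); r2' = ", signif(x$r2_prime, 4), ", S = ", round(x$S, 1),
      ", pairs = ", x$n_pairs, ", correction = ", x$correction, "\n",
      sep = "")
  invisible(x)
}

#' One-call LD-Ne from genotypes
#'
#' Convenience wrapper chaining [ld_pairs()] and [estimate_ne()], with an
#' optional jackknife-over-individuals CI (each individual dropped in turn,
#' the whole r2 summary recomputed, and the point estimate's variability
#' converted to an interval on the log scale).
#'
#' @inheritParams ld_pairs
#' @inheritParams estimate_ne
#' @param ci_method `"parametric"` or `"jackknife"`.
#' @return an `ne_result`.
#' @export
ld_ne <- function(gm, group = NULL, pcrit = 0.05, chrom = NULL,
                  n_chromosomes = NULL, ci_method = "parametric",
                  alpha = 0.05) {
  smry <- ld_r2_summary(gm, group = group, pcrit = pcrit, chrom = chrom)
  res <- estimate_ne(smry, n_chromosomes = n_chromosomes,
                     ci_method = "parametric", alpha = alpha)
  if (identical(ci_method, "jackknife")) {
    g <- if (inherits(gm, "genotype_matrix")) gm$genotypes else as.matrix(gm)
    if (!is.null(group)) g <- g[group, , drop = FALSE]
    n <- nrow(g)
    r2p_jk <- vapply(seq_len(n), function(i) {
      sm <- ld_r2_summary(g[-i, , drop = FALSE], pcrit = pcrit,
                          chrom = if (isTRUE(chrom)) gm$locus_table$chrom)
      sm$r2_mean - (1 / sm$S + 3.19 / sm$S^2)
    }, numeric(1))
    theta_dot <- mean(r2p_jk)
    se <- sqrt((n - 1) / n * sum((r2p_jk - theta_dot)^2))
    z <- stats::qnorm(1 - alpha / 2)
    lo <- res$r2_prime - z * se
    hi <- res$r2_prime + z * se
    corr <- if (res$correction == "chromosome_count_formula")
      0.098 + 0.219 * log(res$n_chromosomes) else 1
    res$ci <- c(ne_from_r2prime(hi), ne_from_r2prime(lo)) / corr
  }
  res
}
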