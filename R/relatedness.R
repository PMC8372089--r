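#' Pairwise moment relatedness from genotype-similarity categories
#'
#' The Wang-style moment estimator of pairwise relatedness for biallelic
#' loci. At each locus a pair's genotypes fall into one of three similarity
#' categories: identical, homozygote-heterozygote (sharing one allele), or
#' opposite homozygotes. Writing phi for the probability that the pair
#' shares exactly one allele pair identical by descent and Delta for the
#' probability of sharing two, the category probabilities are linear in
#' (phi, Delta) with allele-frequency-dependent coefficients:
#'
#'   P(opposite homozygotes) = (1 - phi - Delta) * 2 p^2 q^2
#'   P(homo-het)             = phi * 2pq + (1 - phi - Delta) * 4pq(p^2 + q^2)
#'
#' Summing the category indicators over loci and equating to these
#' expectations (a ratio-of-sums moment fit, which weights each locus by its
#' informativeness) gives estimates of phi and Delta, and the relatedness is
#' r = phi/2 + Delta = 1 - (1 - phi - Delta) - phi/2. The estimator is
#' symmetric in the pair, invariant to allele relabeling, unbiased under
#' Hardy-Weinberg reference frequencies, and can exceed [0, 1] slightly by
#' sampling error (excursions are preserved, not clipped).
#'
#' Expected values: clones 1, full sibs and parent-offspring 0.5, half sibs
#' 0.25, unrelated 0.
#'
#' @param gm a `genotype_matrix` or dosage matrix.
#' @param freq_source optional: a logical/integer index of individuals from
#'   which to estimate reference allele frequencies (default: the whole
#'   sample, matching a within-species analysis), or a numeric vector of
#'   per-locus alternate-allele frequencies.
#' @return object of class `relatedness_matrix`: `estimates` (symmetric
#'   n x n, diagonal NA), `n_loci` (loci used per pair).
#' @export
wang_relatedness <- function(gm, freq_source = NULL) {
  g <- if (inherits(gm, "genotype_matrix")) gm$genotypes else as.matrix(gm)
  n <- nrow(g)
  if (n < 2) stop("need at least 2 individuals")
  if (is.numeric(freq_source) && length(freq_source) == ncol(g) &&
      all(freq_source >= 0 & freq_source <= 1) && !is.integer(freq_source)) {
    p <- freq_source
  } else {
    ref <- if (is.null(freq_source)) g else g[freq_source, , drop = FALSE]
    p <- colSums(ref, na.rm = TRUE) / (2 * colSums(!is.na(ref)))
  }
  q <- 1 - p
  informative <- is.finite(p) & p > 0 & p < 1
  g <- g[, informative, drop = FALSE]
  p <- p[informative]; q <- q[informative]

  w4 <- 2 * p^2 * q^2                 # opposite homozygotes, unrelated
  w2u <- 4 * p * q * (p^2 + q^2)      # homo-het, unrelated
  w2phi <- 2 * p * q                  # homo-het, one pair IBD

  M <- (!is.na(g)) + 0
  Hom0 <- (g == 0L & M == 1) + 0      # ref homozygote indicators
  Hom2 <- (g == 2L & M == 1) + 0
  Het <- (g == 1L & M == 1) + 0
  HomAny <- Hom0 + Hom2

  I4 <- tcrossprod(Hom0, Hom2); I4 <- I4 + t(I4)
  I2 <- tcrossprod(Het, HomAny); I2 <- I2 + t(I2)
  W4 <- tcrossprod(sweep(M, 2, w4, "*"), M)
  W2u <- tcrossprod(sweep(M, 2, w2u, "*"), M)
  W2phi <- tcrossprod(sweep(M, 2, w2phi, "*"), M)
  n_loci <- tcrossprod(M, M)

  u_hat <- I4 / W4                     # estimate of 1 - phi - Delta
  phi_hat <- (I2 - u_hat * W2u) / W2phi
  r <- 1 - u_hat - phi_hat / 2

  none <- n_loci == 0 | W4 == 0 | W2phi == 0
  if (any(none[upper.tri(none)]))
    warning("pair(s) sharing no informative genotyped loci: estimate NA")
  r[none] <- NA_real_
  diag(r) <- NA_real_
  ids <- rownames(g) %||% as.character(seq_len(n))
  dimnames(r) <- list(ids, ids)
  dimnames(n_loci) <- list(ids, ids)
  structure(list(estimates = r, n_loci = n_loci),
            class = "relatedness_matrix")
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  v <- x$estimates[upper.tri(x$estimates)]
  cat("<relatedness_matrix> ", nrow(x$estimates), " individuals; mean r = ",
      signif(mean(v, na.rm = TRUE), 3), ", max r = ",
      signif(max(v, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' Flag highly related pairs
#'
#' Pairs with relatedness strictly greater than the threshold (default 0.4)
#' are flagged as likely first-degree relatives (full siblings or
#' parent-offspring). A pair at exactly the threshold is not flagged. When
#' metadata and/or group assignments are given, each pair is annotated with
#' both members' sampling location and genetic group, supporting checks of
#' whether related pairs co-occur.
#'
#' @param rm a `relatedness_matrix`.
#' @param threshold strict lower bound for flagging (default 0.4).
#' @param metadata optional data.frame with `individual_id`, `location`.
#' @param groups optional named vector or `group_assignment` giving each
#'   individual's genetic group.
#' @return data.frame with `id1`, `id2`, `estimate`, `n_loci` and any
#'   annotation columns; zero rows when nothing exceeds the threshold.
#' @export
find_related_pairs <- function(rm, threshold = 0.4, metadata = NULL,
                               groups = NULL) {
  est <- rm$estimates
  ids <- rownames(est)
  sel <- which(upper.tri(est) & !is.na(est) & est > threshold)
  n <- nrow(est)
  i <- (sel - 1L) %% n + 1L
  j <- (sel - 1L) %/% n + 1L
  out <- data.frame(id1 = ids[i], id2 = ids[j], estimate = est[sel],
                    n_loci = rm$n_loci[sel], stringsAsFactors = FALSE)
  out <- out[order(-out$estimate), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(metadata)) {
    loc <- metadata$location[match(out$id1, metadata$individual_id)]
    out$location1 <- loc
    out$location2 <- metadata$location[match(out$id2, metadata$individual_id)]
  }
  if (!is.null(groups)) {
    if (inherits(groups, "group_assignment")) {
      a <- groups$assignments
      groups <- stats::setNames(a$group, a$individual_id)
    }
    out$group1 <- unname(groups[out$id1])
    out$group2 <- unname(groups[out$id2])
  }
  out
}
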