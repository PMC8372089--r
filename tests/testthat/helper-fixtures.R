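# Shared fixtures and independent oracles, all built in code.

# tiny genotype_matrix from a plain dosage matrix
toy_gm <- function(g, tags = NULL, chrom = NULL, pos = NULL,
                   depth_ref = NULL, depth_alt = NULL) {
  g <- as.matrix(g)
  L <- ncol(g)
  if (L == 0) {
    lt <- data.frame(locus_id = character(0), chrom = character(0),
                     pos = integer(0), tag_id = character(0),
                     ref = character(0), alt = character(0))
    return(genotype_matrix(g, sprintf("i%02d", seq_len(nrow(g))), lt))
  }
  lt <- data.frame(
    locus_id = paste0("t", seq_len(L), "_1"),
    chrom = chrom %||% rep("chr1", L),
    pos = pos %||% seq(100, by = 100, length.out = L),
    tag_id = tags %||% paste0("t", seq_len(L)),
    ref = rep("A", L), alt = rep("C", L), stringsAsFactors = FALSE)
  if (!is.null(tags)) {
    off <- stats::ave(seq_len(L), tags, FUN = seq_along)
    lt$locus_id <- paste0(tags, "_", off)
  }
  genotype_matrix(g, sprintf("i%02d", seq_len(nrow(g))), lt,
                  depth_ref = depth_ref, depth_alt = depth_alt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-population Balding-Nichols sample used across modules
make_two_pop <- function(n_per = 50, L = 2000, F_div = 0.1, seed = 7,
                         missing_rate = 0) {
  m <- pop_model(K = 2, L = L, F_div = F_div, missing_rate = missing_rate)
  f <- draw_source_frequencies(m, seed)
  d <- sample_design(list(
    list(n = n_per, q = c(1, 0), location = "above_dam",
         date = "2019-06-01", label = "p1", length_mean = 300,
         length_sd = 50),
    list(n = n_per, q = c(0, 1), location = "below_dam",
         date = "2018-05-01", label = "p2", length_mean = 200,
         length_sd = 50)))
  s <- simulate_individuals(f, d, m, seed + 1)
  list(model = m, freqs = f, design = d, genotypes = s$genotypes,
       metadata = s$metadata)
}

# Independent Weir-Cockerham (1984) oracle: literal per-locus transcription
# of the variance components with explicit loops, no shared code with the
# package implementation.
oracle_wc_fst <- function(g, groups) {
  groups <- factor(groups)
  r <- nlevels(groups)
  A <- B <- C <- 0
  for (l in seq_len(ncol(g))) {
    ni <- pi <- hi <- numeric(r)
    for (k in seq_len(r)) {
      x <- g[groups == levels(groups)[k], l]
      x <- x[!is.na(x)]
      ni[k] <- length(x)
      pi[k] <- sum(x) / (2 * length(x))
      hi[k] <- mean(x == 1)
    }
    if (any(ni < 1)) next
    nbar <- mean(ni)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    if (nc <= 0) next
    pbar <- sum(ni * pi) / (r * nbar)
    if (pbar <= 0 || pbar >= 1) next
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r -
         hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  A / (A + B + C)
}

# Independent Burrows composite-LD oracle for one locus pair
oracle_burrows_r2 <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  delta <- (sum(x * y) - sum(x) * sum(y) / n) / (n - 1) / 2
  pA <- sum(x) / (2 * n)
  pB <- sum(y) / (2 * n)
  delta^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# fixed 3+3 individuals x 2 loci table used for the exact FST comparison
fst_toy_table <- function() {
  rbind(c(0L, 1L), c(1L, 2L), c(0L, 0L),
        c(2L, 1L), c(1L, 2L), c(2L, 2L))
}
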