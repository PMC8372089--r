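#' Population model for synthetic genotype data
#'
#' Parameters of the Balding-Nichols generator that stands in for the study's
#' RADseq data. `K` source populations diverge from a shared ancestral allele
#' frequency with per-population divergence `F_div` (interpretable as the
#' expected FST between a population and the ancestor). Loci are grouped
#' into multi-SNP RAD tags spread over `n_chromosomes` chromosomes, and a
#' `paralog_fraction` of loci emulate merged duplicate loci (excess
#' heterozygosity with biased read ratios), the failure mode the HDPlot
#' filter is designed to catch.
#'
#' @param K number of source populations (>= 1).
#' @param L number of loci.
#' @param F_div Balding-Nichols divergence parameter in (0, 1); 0 means all
#'   populations share the ancestral frequencies exactly.
#' @param ancestral_maf_range interval within (0, 0.5] from which ancestral
#'   minor-allele frequencies are drawn.
#' @param n_chromosomes number of chromosome labels to spread tags over.
#' @param snps_per_tag_probs probabilities of a tag carrying 1, 2 or 3 SNPs.
#' @param missing_rate per-genotype missing-completely-at-random rate.
#' @param depth_mean mean total read depth per genotype (shifted Poisson,
#'   minimum 1 read).
#' @param paralog_fraction fraction of loci simulated as merged paralogs.
#' @return an object of class `pop_model`.
#' @export
pop_model <- function(K = 2, L = 1000, F_div = 0.1,
                      ancestral_maf_range = c(0.1, 0.5),
                      n_chromosomes = 24,
                      snps_per_tag_probs = c(0.6, 0.3, 0.1),
                      missing_rate = 0.05, depth_mean = 20,
                      paralog_fraction = 0) {
  stopifnot(K >= 1, L >= 1, F_div >= 0, F_div < 1,
            length(ancestral_maf_range) == 2,
            ancestral_maf_range[1] > 0, ancestral_maf_range[2] <= 0.5,
            ancestral_maf_range[1] <= ancestral_maf_range[2],
            n_chromosomes >= 1,
            length(snps_per_tag_probs) == 3, all(snps_per_tag_probs >= 0),
            sum(snps_per_tag_probs) > 0,
            missing_rate >= 0, missing_rate < 1,
            depth_mean > 0, paralog_fraction >= 0, paralog_fraction < 1)
  structure(list(K = K, L = L, F_div = F_div,
                 ancestral_maf_range = ancestral_maf_range,
                 n_chromosomes = n_chromosomes,
                 snps_per_tag_probs = snps_per_tag_probs / sum(snps_per_tag_probs),
                 missing_rate = missing_rate, depth_mean = depth_mean,
                 paralog_fraction = paralog_fraction),
            class = "pop_model")
}

#' Sampling design for synthetic individuals
#'
#' A design is a list of capture cohorts. Each cohort has a size, a sampling
#' location (above or below the barrier), a capture date, an admixture vector
#' `q` over the `K` source populations (a pure individual has a one-hot `q`),
#' a truth label, and a body-length distribution (mean and sd in mm),
#' emulating mixed-stock sampling with group-specific length distributions.
#'
#' @param cohorts list of lists with fields `n`, `q`, `location`, `date`,
#'   `label`, `length_mean`, `length_sd`.
#' @param species species name recorded in the metadata.
#' @return an object of class `sample_design`.
#' @export
sample_design <- function(cohorts, species = "synthetic_fish") {
  for (co in cohorts) {
    stopifnot(co$n >= 0, all(co$q >= 0), abs(sum(co$q) - 1) < 1e-8,
              co$length_mean > 0, co$length_sd >= 0)
  }
  structure(list(cohorts = cohorts, species = species),
            class = "sample_design")
}

#' A ready-made two-population mixed-stock design
#'
#' Mirrors the study system's sampling geometry: a river group found both
#' above and below the barrier, a lake group found only below, and a few
#' admixed individuals below. Group length means differ so that downstream
#' ecological comparisons have signal.
#'
#' @param n_above,n_below_river,n_below_lake,n_admixed cohort sizes.
#' @return a `sample_design` for a K = 2 model.
#' @export
default_design <- function(n_above = 30, n_below_river = 20,
                           n_below_lake = 20, n_admixed = 5) {
  sample_design(list(
    list(n = n_above, q = c(1, 0), location = "above_dam",
         date = "2019-06-15", label = "river", length_mean = 340,
         length_sd = 60),
    list(n = n_below_river, q = c(1, 0), location = "below_dam",
         date = "2018-05-10", label = "river", length_mean = 340,
         length_sd = 60),
    list(n = n_below_lake, q = c(0, 1), location = "below_dam",
         date = "2018-05-10", label = "lake", length_mean = 190,
         length_sd = 50),
    list(n = n_admixed, q = c(0.5, 0.5), location = "below_dam",
         date = "2018-07-01", label = "admixed", length_mean = 260,
         length_sd = 55)))
}

#' Draw per-population allele frequencies under the Balding-Nichols model
#'
#' For each locus an ancestral frequency `p` is drawn uniformly from the
#' ancestral MAF range or its mirror (so reference and alternate alleles are
#' exchangeable), then each population's frequency is drawn from
#' Beta(p(1-F)/F, (1-p)(1-F)/F), whose mean is `p` and whose standardized
#' variance is the divergence parameter `F`. With `F_div = 0` populations
#' share the ancestral frequencies exactly.
#'
#' @param model a [pop_model()].
#' @param seed integer seed; the draw is deterministic given (seed, model).
#' @return K x L matrix of alternate-allele frequencies in (0, 1), with the
#'   ancestral frequencies attached as attribute `ancestral`.
#' @export
draw_source_frequencies <- function(model, seed) {
  stopifnot(inherits(model, "pop_model"))
  set.seed(seed)
  r <- model$ancestral_maf_range
  p <- runif(model$L, r[1], r[2])
  flip <- runif(model$L) < 0.5
  p[flip] <- 1 - p[flip]
  if (model$F_div == 0) {
    freqs <- matrix(rep(p, each = model$K), nrow = model$K)
  } else {
    Fd <- model$F_div
    freqs <- matrix(
      rbeta(model$K * model$L,
            shape1 = rep(p, each = model$K) * (1 - Fd) / Fd,
            shape2 = rep(1 - p, each = model$K) * (1 - Fd) / Fd),
      nrow = model$K)
    ## rbeta can return exact 0/1 for tiny shapes; keep frequencies interior
    freqs <- pmin(pmax(freqs, 1e-9), 1 - 1e-9)
  }
  attr(freqs, "ancestral") <- p
  freqs
}

## locus metadata: tags of 1-3 SNPs, round-robin chromosomes, random positions
make_locus_table <- function(model) {
  sizes <- integer(0)
  total <- 0L
  while (total < model$L) {
    s <- sample.int(3L, 1L, prob = model$snps_per_tag_probs)
    sizes <- c(sizes, min(s, model$L - total))
    total <- total + sizes[length(sizes)]
  }
  tag_idx <- rep(seq_along(sizes), sizes)
  offset <- unlist(lapply(sizes, seq_len))
  chrom_of_tag <- ((seq_along(sizes) - 1L) %% model$n_chromosomes) + 1L
  tag_start <- sample.int(1e7L, length(sizes), replace = TRUE)
  data.frame(
    locus_id = paste0("tag", tag_idx, "_", offset),
    chrom = paste0("chr", chrom_of_tag[tag_idx]),
    pos = tag_start[tag_idx] + (offset - 1L) * 7L,
    tag_id = paste0("tag", tag_idx),
    ref = "A", alt = "C", stringsAsFactors = FALSE)
}

#' Simulate genotyped individuals under a sampling design
#'
#' Genotypes at locus l for an individual with admixture vector q are
#' Binomial(2, sum_k q_k f_kl). Missingness is MCAR at the model's rate.
#' Total read depth per genotype is 1 + Poisson(depth_mean - 1); heterozygote
#' reads split Binomial(total, 0.5), except at paralog-class loci where the
#' alternate-read probability is 0.2 and heterozygosity is inflated (forced
#' heterozygote rate 0.7), emulating merged duplicate loci. Body lengths are
#' Normal(group mean, group sd) truncated at zero.
#'
#' @param freqs K x L frequency matrix from [draw_source_frequencies()].
#' @param design a [sample_design()].
#' @param model the [pop_model()] used to draw `freqs`.
#' @param seed integer seed.
#' @return list with `genotypes` (a `genotype_matrix` with depths) and
#'   `metadata` (a data.frame with `true_group` labels).
#' @export
simulate_individuals <- function(freqs, design, model, seed) {
  stopifnot(inherits(design, "sample_design"), inherits(model, "pop_model"))
  set.seed(seed)
  K <- nrow(freqs); L <- ncol(freqs)
  ns <- vapply(design$cohorts, `[[`, numeric(1), "n")
  n <- sum(ns)
  lt <- make_locus_table(model)
  n_par <- round(model$paralog_fraction * L)
  paralog <- rep(FALSE, L)
  if (n_par > 0) paralog[sample.int(L, n_par)] <- TRUE

  if (n == 0) {
    gm <- genotype_matrix(matrix(integer(0), 0, L), character(0), lt,
                          depth_ref = matrix(0L, 0, L),
                          depth_alt = matrix(0L, 0, L))
    attr(gm, "paralog") <- paralog
    return(list(genotypes = gm,
                metadata = data.frame(individual_id = character(0),
                                      location = character(0),
                                      capture_date = as.Date(character(0)),
                                      total_length_mm = numeric(0),
                                      species = character(0),
                                      true_group = character(0))))
  }

  Qrows <- do.call(rbind, lapply(design$cohorts, function(co) {
    matrix(rep(co$q, each = co$n), nrow = co$n)
  }))
  PI <- Qrows %*% freqs                       # n x L expected alt frequency
  G <- matrix(rbinom(n * L, 2L, PI), n, L)
  if (any(paralog)) {                          # merged-duplicate emulation
    np <- sum(paralog)
    het <- matrix(runif(n * np) < 0.7, n, np)
    sub <- G[, paralog, drop = FALSE]
    sub[het] <- 1L
    sub[!het & sub == 1L] <- ifelse(runif(sum(!het & sub == 1L)) < 0.5, 0L, 2L)
    G[, paralog] <- sub
  }

  total <- matrix(1L + rpois(n * L, model$depth_mean - 1), n, L)
  p_alt_read <- matrix(0.5, n, L)
  p_alt_read[, paralog] <- 0.2
  alt_reads <- matrix(0L, n, L)
  hom_alt <- G == 2L
  alt_reads[hom_alt] <- total[hom_alt]
  is_het <- G == 1L
  alt_reads[is_het] <- rbinom(sum(is_het), total[is_het], p_alt_read[is_het])
  ref_reads <- total - alt_reads

  if (model$missing_rate > 0) {
    mis <- matrix(runif(n * L) < model$missing_rate, n, L)
    G[mis] <- NA_integer_
    ref_reads[mis] <- 0L
    alt_reads[mis] <- 0L
  }

  ids <- sprintf("ind_%03d", seq_len(n))
  md <- do.call(rbind, lapply(seq_along(design$cohorts), function(i) {
    co <- design$cohorts[[i]]
    if (co$n == 0) return(NULL)
    len <- rnorm(co$n, co$length_mean, co$length_sd)
    while (any(len <= 0))
      len[len <= 0] <- rnorm(sum(len <= 0), co$length_mean, co$length_sd)
    data.frame(location = co$location, capture_date = as.Date(co$date),
               total_length_mm = len, species = design$species,
               true_group = co$label, stringsAsFactors = FALSE)
  }))
  md <- cbind(individual_id = ids, md)
  rownames(md) <- NULL

  gm <- genotype_matrix(G, ids, lt, depth_ref = ref_reads,
                        depth_alt = alt_reads)
  attr(gm, "paralog") <- paralog
  list(genotypes = gm, metadata = md)
}

#' Append related individuals to a genotype matrix
#'
#' Spikes pedigree structure into a simulated sample. A parent-offspring pair
#' is a fresh parent drawn from the named source population plus a child that
#' inherits one allele from the parent and one from the population
#' frequencies. A full-sib pair shares two simulated parents. Spiked
#' individuals are appended (never replacing existing ones) and the truth is
#' returned alongside.
#'
#' @param gm a `genotype_matrix` (no depths required; depth matrices, when
#'   present, are extended with constant coverage).
#' @param freqs K x L source frequency matrix.
#' @param pairs_spec data.frame with columns `relationship`
#'   (`"parent_offspring"` or `"full_sib"`), `pop` (source population row in
#'   `freqs`), `count`.
#' @param seed integer seed.
#' @return list with `genotypes` (extended matrix) and `pairs` (data.frame
#'   `id1`, `id2`, `relationship`, `pop`).
#' @export
spike_relatives <- function(gm, freqs, pairs_spec, seed) {
  set.seed(seed)
  L <- ncol(freqs)
  stopifnot(n_loci(gm) == L)
  bad <- setdiff(pairs_spec$relationship, c("parent_offspring", "full_sib"))
  if (length(bad)) stop("unknown relationship: ", paste(bad, collapse = ", "))
  if (nrow(pairs_spec) == 0 || sum(pairs_spec$count) == 0)
    return(list(genotypes = gm,
                pairs = data.frame(id1 = character(0), id2 = character(0),
                                   relationship = character(0),
                                   pop = integer(0))))
  new_g <- list(); ids <- character(0); pairs <- list()
  draw_geno <- function(f) rbinom(L, 2L, f)
  gamete <- function(g) rbinom(L, 1L, g / 2)
  k <- 0L
  for (r in seq_len(nrow(pairs_spec))) {
    rel <- pairs_spec$relationship[r]
    f <- freqs[pairs_spec$pop[r], ]
    for (i in seq_len(pairs_spec$count[r])) {
      k <- k + 1L
      if (rel == "parent_offspring") {
        parent <- draw_geno(f)
        child <- gamete(parent) + rbinom(L, 1L, f)
        id1 <- sprintf("po%03d_parent", k); id2 <- sprintf("po%03d_child", k)
        new_g <- c(new_g, list(parent, child))
      } else {
        pa <- draw_geno(f); pb <- draw_geno(f)
        sib1 <- gamete(pa) + gamete(pb)
        sib2 <- gamete(pa) + gamete(pb)
        id1 <- sprintf("fs%03d_a", k); id2 <- sprintf("fs%03d_b", k)
        new_g <- c(new_g, list(sib1, sib2))
      }
      ids <- c(ids, id1, id2)
      pairs[[k]] <- data.frame(id1 = id1, id2 = id2, relationship = rel,
                               pop = pairs_spec$pop[r])
    }
  }
  add <- do.call(rbind, new_g)
  storage.mode(add) <- "integer"
  G <- rbind(gm$genotypes, add)
  dr <- da <- NULL
  if (!is.null(gm$depth_ref)) {
    dep <- matrix(20L, nrow(add), L)
    a <- matrix(0L, nrow(add), L)
    a[add == 2L] <- dep[add == 2L]
    a[add == 1L] <- rbinom(sum(add == 1L), dep[add == 1L], 0.5)
    dr <- rbind(gm$depth_ref, dep - a)
    da <- rbind(gm$depth_alt, a)
  }
  list(genotypes = genotype_matrix(G, c(gm$individual_ids, ids),
                                   gm$locus_table, depth_ref = dr,
                                   depth_alt = da),
       pairs = do.call(rbind, pairs))
}

#' Simulate a single isolated Wright-Fisher population
#'
#' Individual-based forward simulation of `n_ind` diploids at `L` unlinked
#' biallelic loci under random mating, used to generate data with the
#' drift-generated linkage disequilibrium that the LD-based Ne estimator
#' measures. Returns the final-generation genotype matrix.
#'
#' @param n_ind diploid population size (the true Ne under random mating).
#' @param L number of unlinked loci.
#' @param generations number of non-overlapping generations to run; LD among
#'   unlinked loci equilibrates within a few tens of generations.
#' @param init_freq_range range of initial allele frequencies.
#' @param seed integer seed.
#' @return integer dosage matrix, `n_ind` x `L`.
#' @export
simulate_wf_population <- function(n_ind, L, generations = 100,
                                   init_freq_range = c(0.2, 0.8), seed = 1) {
  set.seed(seed)
  p0 <- runif(L, init_freq_range[1], init_freq_range[2])
  G <- matrix(rbinom(n_ind * L, 2L, rep(p0, each = n_ind)), n_ind, L)
  for (g in seq_len(generations)) {
    mothers <- sample.int(n_ind, n_ind, replace = TRUE)
    fathers <- sample.int(n_ind, n_ind, replace = TRUE)
    G <- matrix(rbinom(n_ind * L, 1L, G[mothers, ] / 2), n_ind, L) +
      matrix(rbinom(n_ind * L, 1L, G[fathers, ] / 2), n_ind, L)
  }
  storage.mode(G) <- "integer"
  G
}
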