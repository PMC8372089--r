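## FilterReport helpers ------------------------------------------------------

removed_records <- function(ids, type, reason) {
  data.frame(id = as.character(ids), type = rep_len(type, length(ids)),
             reason = rep_len(reason, length(ids)), stringsAsFactors = FALSE)
}

new_filter_report <- function(stage, before_loci, after_loci, before_ind,
                              after_ind, removed, extra = NULL) {
  structure(list(stage = stage,
                 counts = data.frame(stage = stage,
                                     loci_before = before_loci,
                                     loci_after = after_loci,
                                     individuals_before = before_ind,
                                     individuals_after = after_ind),
                 removed = removed, extra = extra),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Call-rate filter for loci and individuals
#'
#' Removes loci genotyped in fewer than `locus_min` of individuals, then
#' individuals genotyped at fewer than `indiv_min` of the remaining loci.
#' Removal is strict less-than: a locus genotyped in exactly 70% of
#' individuals is retained. Loci are filtered first, so an individual's call
#' rate is judged against the locus-filtered matrix.
#'
#' @param gm a `genotype_matrix`.
#' @param locus_min,indiv_min call-rate thresholds in (0, 1].
#' @return list with `genotypes` (filtered matrix) and `report`
#'   (a `filter_report`).
#' @export
filter_call_rate <- function(gm, locus_min = 0.70, indiv_min = 0.70) {
  stopifnot(locus_min > 0, locus_min <= 1, indiv_min > 0, indiv_min <= 1)
  g <- gm$genotypes
  locus_cr <- colMeans(!is.na(g))
  keep_l <- locus_cr >= locus_min
  removed <- removed_records(gm$locus_table$locus_id[!keep_l], "locus",
                             "call_rate")
  gm2 <- subset_genotypes(gm, loci = keep_l)
  ind_cr <- if (n_loci(gm2)) rowMeans(!is.na(gm2$genotypes)) else
    rep(0, n_individuals(gm2))
  keep_i <- ind_cr >= indiv_min
  removed <- rbind(removed,
                   removed_records(gm2$individual_ids[!keep_i],
                                   "individual", "call_rate"))
  gm3 <- subset_genotypes(gm2, individuals = keep_i)
  list(genotypes = gm3,
       report = new_filter_report("call_rate", n_loci(gm), n_loci(gm3),
                                  n_individuals(gm), n_individuals(gm3),
                                  removed))
}

#' Minor allele count filter
#'
#' Counts copies of each locus's rarer allele over non-missing genotypes and
#' removes loci with fewer than `min_count` copies. Monomorphic loci have a
#' minor allele count of zero and are always removed for `min_count >= 1`.
#'
#' @param gm a `genotype_matrix`.
#' @param min_count minimum minor allele count to retain a locus (>= 1).
#' @return list with `genotypes` and `report`.
#' @export
filter_mac <- function(gm, min_count = 3) {
  stopifnot(min_count >= 1)
  g <- gm$genotypes
  alt <- colSums(g, na.rm = TRUE)
  tot <- 2 * colSums(!is.na(g))
  mac <- pmin(alt, tot - alt)
  keep <- mac >= min_count
  removed <- removed_records(gm$locus_table$locus_id[!keep], "locus", "mac")
  gm2 <- subset_genotypes(gm, loci = keep)
  list(genotypes = gm2,
       report = new_filter_report("mac", n_loci(gm), n_loci(gm2),
                                  n_individuals(gm), n_individuals(gm2),
                                  removed))
}

#' Per-locus HDPlot statistics
#'
#' For each locus, `H` is the proportion of heterozygotes among genotyped
#' individuals and `D` is the z-score of read-ratio imbalance in
#' heterozygotes: D = (sum_ref - sum_alt) / sqrt(sum_ref + sum_alt), where
#' the sums run over reads of all heterozygous calls at the locus (the
#' binomial-0.5 standardization). Loci with no heterozygotes get D = 0.
#' Merged paralogs show up as high-H, high-|D| outliers.
#'
#' @param gm a `genotype_matrix` with depths.
#' @return data.frame with columns `locus_id`, `H`, `D`, `n_het`.
#' @export
hdplot_stats <- function(gm) {
  if (is.null(gm$depth_ref))
    stop("HDPlot needs read depths; this matrix has none. ",
         "Skip the HDPlot stage (filter_chain(hdplot = FALSE)) for ",
         "depth-free data.")
  g <- gm$genotypes
  het <- !is.na(g) & g == 1L
  H <- colSums(het) / pmax(colSums(!is.na(g)), 1L)
  sum_ref <- colSums(gm$depth_ref * het)
  sum_alt <- colSums(gm$depth_alt * het)
  tot <- sum_ref + sum_alt
  D <- ifelse(tot > 0, (sum_ref - sum_alt) / sqrt(tot), 0)
  data.frame(locus_id = gm$locus_table$locus_id, H = H, D = D,
             n_het = colSums(het), stringsAsFactors = FALSE)
}

#' HDPlot paralog filter
#'
#' Removes loci with heterozygosity H strictly greater than `h_max` or
#' absolute read-ratio deviation |D| strictly greater than `d_max`
#' (see [hdplot_stats()]). A locus at exactly the threshold is retained.
#'
#' @param gm a `genotype_matrix` with depths.
#' @param h_max heterozygosity ceiling (default 0.60).
#' @param d_max two-sided read-ratio deviation ceiling (default 5).
#' @return list with `genotypes` and `report`; the report's `extra` holds
#'   the per-locus H/D table.
#' @export
hdplot_filter <- function(gm, h_max = 0.60, d_max = 5.0) {
  hd <- hdplot_stats(gm)
  keep <- hd$H <= h_max & abs(hd$D) <= d_max
  reason <- ifelse(hd$H > h_max, "hdplot_H", "hdplot_D")
  removed <- removed_records(hd$locus_id[!keep], "locus", reason[!keep])
  gm2 <- subset_genotypes(gm, loci = keep)
  list(genotypes = gm2,
       report = new_filter_report("hdplot", n_loci(gm), n_loci(gm2),
                                  n_individuals(gm), n_individuals(gm2),
                                  removed, extra = hd))
}

#' Keep one SNP per RAD tag
#'
#' Within each tag, retains only the SNP with the highest minor allele
#' frequency; ties are broken by smallest position, then lexicographically by
#' locus id. Loci on the same tag may be physically linked, so downstream
#' statistics assume this filter has run. The retained loci keep their
#' original order.
#'
#' @param gm a `genotype_matrix` with `tag_id` populated.
#' @return list with `genotypes` and `report`.
#' @export
one_snp_per_tag <- function(gm) {
  lt <- gm$locus_table
  m <- maf(gm)
  ord <- order(lt$tag_id, -m, lt$pos, lt$locus_id)
  first <- !duplicated(lt$tag_id[ord])
  keep_idx <- sort(ord[first])                    # preserve original order
  keep <- seq_len(n_loci(gm)) %in% keep_idx
  removed <- removed_records(lt$locus_id[!keep], "locus",
                             "one_snp_per_tag")
  gm2 <- subset_genotypes(gm, loci = keep)
  list(genotypes = gm2,
       report = new_filter_report("one_snp_per_tag", n_loci(gm), n_loci(gm2),
                                  n_individuals(gm), n_individuals(gm2),
                                  removed))
}

#' Run the full post-genotyping filter chain
#'
#' Fixed stage order: locus call rate, individual call rate, minor allele
#' count, HDPlot, one SNP per tag. Each stage acts on the previous stage's
#' output (so MAC is recomputed after individual removal). Rerunning the
#' chain on its own output is the identity.
#'
#' @param gm a `genotype_matrix`.
#' @param locus_min,indiv_min,min_mac,h_max,d_max stage thresholds.
#' @param hdplot logical; set `FALSE` to skip HDPlot when depths are absent.
#' @return list with `genotypes` and `report` (combined stage table,
#'   per-stage removals, and HDPlot statistics when run).
#' @export
filter_chain <- function(gm, locus_min = 0.70, indiv_min = 0.70, min_mac = 3,
                         h_max = 0.60, d_max = 5.0, hdplot = TRUE) {
  stages <- list()
  s1 <- filter_call_rate(gm, locus_min, indiv_min)
  stages$call_rate <- s1$report
  cur <- s1$genotypes
  s2 <- filter_mac(cur, min_mac)
  stages$mac <- s2$report
  cur <- s2$genotypes
  hd <- NULL
  if (hdplot) {
    s3 <- hdplot_filter(cur, h_max, d_max)
    stages$hdplot <- s3$report
    hd <- s3$report$extra
    cur <- s3$genotypes
  }
  s4 <- one_snp_per_tag(cur)
  stages$one_snp_per_tag <- s4$report
  cur <- s4$genotypes
  counts <- do.call(rbind, lapply(stages, `[[`, "counts"))
  rownames(counts) <- NULL
  removed <- do.call(rbind, lapply(stages, `[[`, "removed"))
  rownames(removed) <- NULL
  log_msg("filter chain: ", n_loci(gm), " -> ", n_loci(cur), " loci; ",
          n_individuals(gm), " -> ", n_individuals(cur), " individuals")
  list(genotypes = cur,
       report = structure(list(stage = "chain", counts = counts,
                               removed = removed, extra = hd),
                          class = "filter_report"))
}
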