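#' Build and validate a pipeline configuration
#'
#' All thresholds default to the study values: 70% locus and individual call
#' rates, minor allele count 3, HDPlot H 0.60 and |D| 5, LD-Ne p-crit 0.05,
#' Q-score assignment cutoff 0.5 and admixture cutoff 0.7, relatedness
#' threshold 0.4, alpha 0.05 for length tests and 0.01 for the
#' differentiation test. The scenario grid defaults to the full
#' 2 x 4 design; shrink it (and the synthetic-data sizes) for quick runs.
#'
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param model a [pop_model()] for the synthetic data stage.
#' @param design a [sample_design()].
#' @param locus_min,indiv_min,min_mac,h_max,d_max filter thresholds.
#' @param pcrit LD-Ne allele-frequency screen.
#' @param assign_cutoff,admix_cutoff Q-score thresholds.
#' @param relatedness_threshold related-pair flag threshold.
#' @param alpha_lengths,alpha_diff significance levels.
#' @param K_range candidate K values for cross-validation.
#' @param grid list of arguments for [run_grid()] (NULL skips the
#'   simulation-grid stage).
#' @param n_chromosomes chromosome count for the Ne bias correction.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            model = pop_model(K = 2, L = 2000, F_div = 0.1,
                                              missing_rate = 0.05,
                                              paralog_fraction = 0.03),
                            design = default_design(),
                            locus_min = 0.70, indiv_min = 0.70, min_mac = 3,
                            h_max = 0.60, d_max = 5.0, pcrit = 0.05,
                            assign_cutoff = 0.5, admix_cutoff = 0.7,
                            relatedness_threshold = 0.4,
                            alpha_lengths = 0.05, alpha_diff = 0.01,
                            K_range = 1:5,
                            grid = list(Ne_values = c(100, 1000),
                                        m_values = c(0, 0.01, 0.05, 0.1),
                                        reps = 10),
                            n_chromosomes = 24) {
  check_frac <- function(x, nm, lo = 0, hi = 1) {
    if (!is.numeric(x) || length(x) != 1 || x <= lo || x > hi)
      stop("config error: ", nm, " must be a number in (", lo, ", ", hi, "]")
  }
  check_frac(locus_min, "locus_min"); check_frac(indiv_min, "indiv_min")
  check_frac(h_max, "h_max"); check_frac(pcrit, "pcrit")
  check_frac(assign_cutoff, "assign_cutoff")
  check_frac(admix_cutoff, "admix_cutoff")
  check_frac(alpha_lengths, "alpha_lengths")
  check_frac(alpha_diff, "alpha_diff")
  if (!is.numeric(min_mac) || min_mac < 1 || min_mac != round(min_mac))
    stop("config error: min_mac must be an integer >= 1")
  if (d_max <= 0) stop("config error: d_max must be positive")
  if (relatedness_threshold < 0)
    stop("config error: relatedness_threshold must be non-negative")
  stopifnot(inherits(model, "pop_model"), inherits(design, "sample_design"))
  structure(as.list(environment())[c(
    "seed", "model", "design", "locus_min", "indiv_min", "min_mac",
    "h_max", "d_max", "pcrit", "assign_cutoff", "admix_cutoff",
    "relatedness_threshold", "alpha_lengths", "alpha_diff", "K_range",
    "grid", "n_chromosomes")], class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages in order — simulate data, filter, differentiation and
#' diversity on the sampled locations, ancestry inference with K selection,
#' Q-score group reassignment, the same statistics on the reformed groups,
#' LD-Ne, relatedness, the barrier simulation grid with the
#' empirical-vs-simulated comparison, and ecological group comparisons —
#' writing every table under `out_dir`. Re-running with the same config
#' reproduces all outputs bit for bit.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 8)
  tsv <- function(d, name) utils::write.table(
    d, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  res <- list()

  log_msg("stage 1/8: synthetic data")
  freqs <- draw_source_frequencies(config$model, seeds[1])
  sim <- simulate_individuals(freqs, config$design, config$model, seeds[2])
  write_genotypes(sim$genotypes, file.path(out_dir, "genotypes.vcf"))
  write_metadata(sim$metadata, file.path(out_dir, "metadata.tsv"))
  res$freqs <- freqs; res$sim <- sim

  log_msg("stage 2/8: filters")
  filt <- filter_chain(sim$genotypes, config$locus_min, config$indiv_min,
                       config$min_mac, config$h_max, config$d_max)
  gm <- filt$genotypes
  jsonlite::write_json(
    list(counts = filt$report$counts, removed = filt$report$removed),
    file.path(out_dir, "filter_report.json"), dataframe = "rows",
    auto_unbox = TRUE, digits = NA)
  res$filter <- filt

  md <- sim$metadata[match(gm$individual_ids, sim$metadata$individual_id), ]
  loc <- md$location

  log_msg("stage 3/8: location-based statistics")
  res$fst_location <- wc_fst(gm, loc)
  res$div_location <- diversity_summary(gm, loc)
  res$diff_test <- differentiation_test(gm, loc, n_perm = 999,
                                        alpha = config$alpha_diff,
                                        seed = seeds[3])
  tsv(cbind(res$div_location,
            fst = res$fst_location$theta,
            diff_p = res$diff_test$p_value), "stats_by_location.tsv")

  log_msg("stage 4/8: ancestry")
  ks <- select_K(gm, config$K_range, seed = seeds[4])
  fit <- fit_admixture(gm, ks$best_K, seed = seeds[4])
  res$select_K <- ks; res$ancestry <- fit
  tsv(data.frame(individual_id = gm$individual_ids, fit$Q), "q_matrix.tsv")

  log_msg("stage 5/8: group reassignment + regrouped statistics")
  asg <- assign_groups(fit, config$assign_cutoff, config$admix_cutoff,
                       metadata = md)
  res$assignment <- asg
  tsv(asg$assignments, "group_assignments.tsv")
  grp <- asg$assignments$group
  if (length(unique(grp)) >= 2 && min(table(grp)) >= 2) {
    res$fst_group <- wc_fst(gm, grp)
    res$div_group <- diversity_summary(gm, grp)
    tsv(cbind(res$div_group, fst = res$fst_group$theta),
        "stats_by_genetic_group.tsv")
  }

  log_msg("stage 6/8: effective population size")
  ne_rows <- lapply(unique(grp), function(g) {
    sel <- grp == g
    if (sum(sel) < 10) return(NULL)
    ne <- tryCatch(
      ld_ne(gm, group = sel, pcrit = config$pcrit,
            n_chromosomes = config$n_chromosomes),
      error = function(e) NULL)
    if (is.null(ne)) return(NULL)
    data.frame(group = g, n = sum(sel), ne = ne$ne, ci_low = ne$ci[1],
               ci_high = ne$ci[2], r2_prime = ne$r2_prime,
               correction = ne$correction)
  })
  res$ne <- do.call(rbind, ne_rows)
  if (!is.null(res$ne)) tsv(res$ne, "ne_by_group.tsv")

  log_msg("stage 7/8: relatedness")
  rm_ <- wang_relatedness(gm)
  rel <- find_related_pairs(rm_, config$relatedness_threshold,
                            metadata = md, groups = asg)
  res$relatedness <- rel
  tsv(rel, "related_pairs.tsv")

  log_msg("stage 8/8: barrier simulations + ecology")
  if (!is.null(config$grid)) {
    grid_args <- config$grid
    grid_args$seed <- seeds[5]
    res$grid <- do.call(run_grid, grid_args)
    tsv(res$grid$results, "sim_grid_results.tsv")
    tsv(res$grid$summary, "sim_grid_summary.tsv")
    ne_focal <- if (!is.null(res$ne)) min(res$ne$ne[is.finite(res$ne$ne)],
                                          na.rm = TRUE) else
      res$grid$params$Ne_values[1]
    theta_for_compare <- if (!is.null(res$fst_group))
      res$fst_group$theta else res$fst_location$theta
    res$comparison <- compare_empirical(theta_for_compare, res$grid,
                                        ne_focal = ne_focal)
    jsonlite::write_json(res$comparison,
                         file.path(out_dir, "empirical_vs_simulated.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if (length(unique(grp)) >= 2 && min(table(grp)) >= 3) {
    res$lengths <- compare_lengths(md, grp, alpha = config$alpha_lengths)
    tsv(res$lengths$per_group, "length_comparison_groups.tsv")
  }
  res$proportions <- group_proportions_by_event(md, grp)
  tsv(res$proportions, "group_proportions_by_event.tsv")

  run_info <- list(package_version = as.character(
    utils::packageVersion("fragpop")), seed = config$seed,
    config = config_fingerprint(config))
  jsonlite::write_json(run_info, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA)
  log_msg("pipeline complete: ", out_dir)
  invisible(res)
}

## compact provenance echo of the thresholds actually used
config_fingerprint <- function(config) {
  scal <- config[c("seed", "locus_min", "indiv_min", "min_mac", "h_max",
                   "d_max", "pcrit", "assign_cutoff", "admix_cutoff",
                   "relatedness_threshold", "alpha_lengths", "alpha_diff",
                   "n_chromosomes")]
  scal$K_range <- paste(range(config$K_range), collapse = "-")
  scal$model <- unclass(config$model)
  scal$grid <- config$grid
  scal
}
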