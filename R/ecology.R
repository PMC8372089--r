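#' Compare body lengths between genetic groups
#'
#' Two groups: Student's two-sample t test when Levene's test (centered on
#' the mean) finds the variances homogeneous at `alpha`, Welch's unequal
#' variances t test otherwise. Three or more groups: one-way ANOVA followed
#' by Tukey's HSD for the pairwise contrasts. Shapiro-Wilk normality checks
#' per group and the Levene result are recorded so the test choice is a pure
#' function of the recorded assumption checks, and the report carries every
#' quantity needed to recompute the statistic by hand.
#'
#' @param metadata data.frame with `total_length_mm` (and `individual_id`).
#' @param group_labels group per individual; default `metadata$true_group`.
#' @param alpha significance level (default 0.05).
#' @return object of class `length_test_report`: per-group summaries,
#'   assumption checks, `test` used, `statistic`, `p_value`, `significant`,
#'   and for ANOVA a `tukey` table of pairwise comparisons.
#' @export
compare_lengths <- function(metadata, group_labels = NULL, alpha = 0.05) {
  len <- metadata$total_length_mm
  grp <- factor(group_labels %||% metadata$true_group)
  ok <- !is.na(len) & !is.na(grp)
  len <- len[ok]; grp <- droplevels(grp[ok])
  sizes <- table(grp)
  if (nlevels(grp) < 2) stop("need >= 2 groups")
  if (any(sizes < 3))
    stop("group(s) with n < 3: ",
         paste(names(sizes)[sizes < 3], collapse = ", "))
  per_group <- data.frame(group = levels(grp), n = as.integer(sizes),
                          mean = as.numeric(tapply(len, grp, mean)),
                          sd = as.numeric(tapply(len, grp, sd)))
  shapiro <- lapply(levels(grp), function(lv) {
    x <- len[grp == lv]
    if (length(unique(x)) < 3) return(list(p.value = NA_real_))
    stats::shapiro.test(x)
  })
  shapiro_p <- vapply(shapiro, function(s) s$p.value, numeric(1))
  levene <- car::leveneTest(len ~ grp, center = mean)
  levene_p <- levene[["Pr(>F)"]][1]
  equal_var <- is.na(levene_p) || levene_p > alpha

  tukey <- NULL
  if (nlevels(grp) == 2) {
    tt <- stats::t.test(len ~ grp, var.equal = equal_var)
    test <- if (equal_var) "student_t" else "welch_t"
    statistic <- unname(tt$statistic)
    p_value <- tt$p.value
  } else {
    fit <- stats::aov(len ~ grp)
    an <- summary(fit)[[1]]
    statistic <- an[["F value"]][1]
    p_value <- an[["Pr(>F)"]][1]
    test <- "anova_tukey"
    tk <- stats::TukeyHSD(fit)$grp
    tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                        p_adj = tk[, "p adj"],
                        significant = tk[, "p adj"] <= alpha,
                        row.names = NULL)
  }
  structure(list(per_group = per_group, shapiro_p = shapiro_p,
                 levene_p = levene_p, equal_variances = equal_var,
                 test = test, statistic = statistic, p_value = p_value,
                 alpha = alpha, significant = p_value <= alpha,
                 tukey = tukey),
            class = "length_test_report")
}

#' @export
print.length_test_report <- function(x, ...) {
  print(x$per_group, row.names = FALSE, digits = 4)
  cat(x$test, ": statistic = ", signif(x$statistic, 4), ", p = ",
      signif(x$p_value, 3),
      if (x$significant) " (significant)" else " (ns)", "\n", sep = "")
  if (!is.null(x$tukey)) print(x$tukey, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Genetic-group proportions by sampling event
#'
#' Descriptive summary of the composition of each capture event: counts and
#' proportions of each genetic group per (date, location). Proportions sum
#' to 1 within an event; no statistical test is performed (sampling effort
#' varies across events).
#'
#' @param metadata data.frame with `capture_date`, `location`,
#'   `individual_id`.
#' @param group_labels genetic group per individual; default
#'   `metadata$true_group`.
#' @return data.frame with `capture_date`, `location`, `group`, `count`,
#'   `proportion`.
#' @export
group_proportions_by_event <- function(metadata, group_labels = NULL) {
  grp <- group_labels %||% metadata$true_group
  if (anyNA(metadata$capture_date)) stop("capture_date required")
  tab <- as.data.frame(table(capture_date = as.character(metadata$capture_date),
                             location = metadata$location, group = grp),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "count"
  tot <- stats::ave(tab$count, tab$capture_date, tab$location, FUN = sum)
  tab <- tab[tot > 0, , drop = FALSE]
  tot <- tot[tot > 0]
  tab$proportion <- tab$count / tot
  tab$capture_date <- as.Date(tab$capture_date)
  tab <- tab[order(tab$capture_date, tab$location, tab$group), ]
  rownames(tab) <- NULL
  tab
}
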