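#' Genotype matrix container
#'
#' The internal data model for SNP genotypes: an individuals x loci matrix of
#' alternate-allele dosages (0, 1, 2; `NA` = missing), a per-locus metadata
#' table, and optional per-genotype read depths. Loci live on RAD tags; a tag
#' may carry several SNPs and the tag identity is what the one-SNP-per-tag
#' filter operates on.
#'
#' @param genotypes integer matrix, individuals x loci, entries in
#'   \{0, 1, 2, NA\}.
#' @param individual_ids character vector, one id per row.
#' @param locus_table data.frame with columns `locus_id`, `chrom`, `pos`,
#'   `tag_id`, `ref`, `alt`; one row per locus (column of `genotypes`).
#' @param depth_ref,depth_alt optional non-negative integer matrices of the
#'   same shape as `genotypes` holding reference / alternate read counts.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, individual_ids, locus_table,
                            depth_ref = NULL, depth_alt = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  rownames(genotypes) <- individual_ids
  colnames(genotypes) <- locus_table$locus_id
  gm <- structure(
    list(genotypes = genotypes,
         individual_ids = as.character(individual_ids),
         locus_table = as.data.frame(locus_table),
         depth_ref = depth_ref,
         depth_alt = depth_alt),
    class = "genotype_matrix")
  validate_genotype_matrix(gm)
  gm
}

#' Validate a genotype_matrix against its invariants
#'
#' Checks dosage codes, unique positive locus ids/positions, and that any
#' genotype with total read depth zero is recorded as missing.
#'
#' @param gm a `genotype_matrix`.
#' @return `gm`, invisibly; errors on violation.
#' @export
validate_genotype_matrix <- function(gm) {
  g <- gm$genotypes
  if (nrow(g) != length(gm$individual_ids))
    stop("genotype rows do not match individual_ids")
  if (ncol(g) != nrow(gm$locus_table))
    stop("genotype columns do not match locus_table rows")
  bad <- g[!is.na(g)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("non-missing genotype codes must be in {0,1,2}")
  lt <- gm$locus_table
  req <- c("locus_id", "chrom", "pos", "tag_id", "ref", "alt")
  miss <- setdiff(req, names(lt))
  if (length(miss)) stop("locus_table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(lt$locus_id)) stop("locus_ids must be unique")
  if (nrow(lt) && any(!is.finite(lt$pos) | lt$pos < 1))
    stop("positions must be positive integers")
  if (!is.null(gm$depth_ref)) {
    if (is.null(gm$depth_alt)) stop("depth_ref present without depth_alt")
    if (!all(dim(gm$depth_ref) == dim(g)) || !all(dim(gm$depth_alt) == dim(g)))
      stop("depth matrices must match genotype dimensions")
    if (any(gm$depth_ref < 0, na.rm = TRUE) || any(gm$depth_alt < 0, na.rm = TRUE))
      stop("read depths must be non-negative")
    tot <- gm$depth_ref + gm$depth_alt
    if (any(tot == 0 & !is.na(g)))
      stop("genotypes with total depth 0 must be missing")
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", n_individuals(x), " individuals x ",
      n_loci(x), " loci\n", sep = "")
  cat("  missing: ", sprintf("%.1f%%", 100 * mean(is.na(x$genotypes))),
      "; depths: ", if (is.null(x$depth_ref)) "absent" else "present",
      "\n", sep = "")
  invisible(x)
}

#' @rdname genotype_matrix
#' @export
n_individuals <- function(gm) nrow(gm$genotypes)

#' @rdname genotype_matrix
#' @export
n_loci <- function(gm) ncol(gm$genotypes)

#' Per-locus allele frequencies
#'
#' `alt_freq()` is the alternate-allele frequency over non-missing genotypes;
#' `maf()` folds it into the minor-allele frequency, which lies in [0, 0.5].
#'
#' @param gm a `genotype_matrix` or plain dosage matrix.
#' @return numeric vector, one value per locus (NaN where no genotypes).
#' @export
alt_freq <- function(gm) {
  g <- if (inherits(gm, "genotype_matrix")) gm$genotypes else gm
  colSums(g, na.rm = TRUE) / (2 * colSums(!is.na(g)))
}

#' @rdname alt_freq
#' @export
maf <- function(gm) {
  p <- alt_freq(gm)
  pmin(p, 1 - p)
}

#' Subset a genotype matrix
#'
#' Subsetting preserves the order of the retained individuals and loci.
#'
#' @param gm a `genotype_matrix`.
#' @param loci,individuals logical or integer index into loci / individuals.
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, loci = NULL, individuals = NULL) {
  li <- loci %||% seq_len(n_loci(gm))
  ii <- individuals %||% seq_len(n_individuals(gm))
  genotype_matrix(
    gm$genotypes[ii, li, drop = FALSE],
    gm$individual_ids[ii],
    gm$locus_table[li, , drop = FALSE],
    depth_ref = if (!is.null(gm$depth_ref)) gm$depth_ref[ii, li, drop = FALSE],
    depth_alt = if (!is.null(gm$depth_alt)) gm$depth_alt[ii, li, drop = FALSE])
}
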