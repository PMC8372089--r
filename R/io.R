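#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses a VCF v4.x file (via \pkg{vcfR}) into a [genotype_matrix()].
#' Only biallelic SNP records are accepted; multiallelic records are skipped
#' with a warning rather than split. Genotype codes are alternate-allele
#' dosages; `./.` maps to missing. When an AD field is present, per-genotype
#' ref/alt read depths are retained.
#'
#' RAD tag identity is taken from the VCF ID column: everything before the
#' last underscore is the tag id (the convention [write_genotypes()] emits,
#' `<tag>_<offset>`). Records with a missing ID fall back to `CHROM:POS` as
#' both locus and tag id. Override the dialect with `tag_regex`, a regex whose
#' first capture group extracts the tag id.
#'
#' @param vcf_path path to a VCF file.
#' @param tag_regex optional regex with one capture group applied to the ID
#'   column to extract the tag id; default strips the final `_<offset>`.
#' @return a `genotype_matrix`; depths present iff the VCF carries AD.
#' @export
read_genotypes <- function(vcf_path, tag_regex = "^(.*)_[^_]*$") {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    samples <- colnames(vcf@gt)[-1] %||% character(0)
    return(genotype_matrix(
      matrix(integer(0), nrow = length(samples), ncol = 0),
      samples,
      data.frame(locus_id = character(0), chrom = character(0),
                 pos = integer(0), tag_id = character(0),
                 ref = character(0), alt = character(0))))
  }
  biallelic <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  if (any(!biallelic)) {
    warning(sum(!biallelic), " non-biallelic-SNP record(s) skipped")
    vcf <- vcf[biallelic, ]
    fix <- fix[biallelic, , drop = FALSE]
  }
  key <- paste(fix$CHROM, fix$POS)
  if (anyDuplicated(key))
    stop("duplicate CHROM/POS records in ", vcf_path, ": ",
         key[duplicated(key)][1])
  pos <- as.integer(fix$POS)
  id <- fix$ID
  no_id <- is.na(id) | id == "." | id == ""
  id[no_id] <- paste0(fix$CHROM[no_id], ":", pos[no_id])
  tag <- ifelse(grepl(tag_regex, id), sub(tag_regex, "\\1", id), id)
  tag[no_id] <- id[no_id]

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", vcf_path)
  gt_core <- sub(":.*$", "", gt)
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  miss <- is.na(gt_core) | gt_core %in% c("./.", ".|.", ".")
  known <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L,
             "0|1" = 1L, "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  vals <- known[gt_core[!miss]]
  if (anyNA(vals)) {
    bad <- which(!miss, arr.ind = TRUE)[which(is.na(vals))[1], ]
    stop("malformed GT '", gt_core[!miss][which(is.na(vals))[1]],
         "' at record ", rownames(gt)[bad[1]] %||% bad[1],
         ", sample ", colnames(gt)[bad[2]])
  }
  dose[!miss] <- vals

  depth_ref <- depth_alt <- NULL
  fmt_has_ad <- any(grepl("(^|:)AD(:|$)", vcf@gt[, "FORMAT"]))
  if (fmt_has_ad) {
    ad <- vcfR::extract.gt(vcf, element = "AD")
    dr <- suppressWarnings(as.integer(sub(",.*$", "", ad)))
    da <- suppressWarnings(as.integer(sub("^[^,]*,", "", ad)))
    depth_ref <- t(matrix(ifelse(is.na(dr), 0L, dr), nrow = nrow(ad)))
    depth_alt <- t(matrix(ifelse(is.na(da), 0L, da), nrow = nrow(ad)))
    zero <- depth_ref + depth_alt == 0 & !is.na(t(dose))
    if (any(zero)) {
      warning(sum(zero), " call(s) with AD totalling 0 set to missing")
      dose[t(zero)] <- NA_integer_
    }
  }

  locus_table <- data.frame(
    locus_id = id, chrom = fix$CHROM, pos = pos, tag_id = tag,
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  genotype_matrix(t(dose), colnames(gt), locus_table,
                  depth_ref = depth_ref, depth_alt = depth_alt)
}

#' Write a genotype matrix to a VCF v4.2 file
#'
#' Emits GT (and AD when depths are present). The ID column carries the
#' locus id, which under the package convention encodes the RAD tag as
#' `<tag>_<offset>` so that tag identity survives a round trip.
#'
#' @param gm a `genotype_matrix`.
#' @param vcf_path output path (plain text).
#' @return `vcf_path`, invisibly.
#' @export
write_genotypes <- function(gm, vcf_path) {
  validate_genotype_matrix(gm)
  lt <- gm$locus_table
  has_ad <- !is.null(gm$depth_ref)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=fragpop",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_ad)
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$individual_ids), collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$genotypes + 1L],
                   nrow = n_individuals(gm))
  gt_str[is.na(gm$genotypes)] <- "./."
  if (has_ad) {
    ad_str <- matrix(paste0(gm$depth_ref, ",", gm$depth_alt),
                     nrow = n_individuals(gm))
    gt_str <- matrix(paste0(gt_str, ":", ad_str), nrow = n_individuals(gm))
  }
  fmt <- if (has_ad) "GT:AD" else "GT"
  body <- if (n_loci(gm)) {
    vapply(seq_len(n_loci(gm)), function(l) {
      paste(c(lt$chrom[l], lt$pos[l], lt$locus_id[l], lt$ref[l], lt$alt[l],
              ".", "PASS", ".", fmt, gt_str[, l]), collapse = "\t")
    }, character(1))
  } else character(0)
  con <- tryCatch(file(vcf_path, "w"),
                  error = function(e) stop("cannot write ", vcf_path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(vcf_path)
}

#' Read a sample metadata table
#'
#' Tab-separated with a named header; required columns are `individual_id`,
#' `location`, `capture_date`, `total_length_mm`, `species`; `true_group` is
#' optional (carried by synthetic data). Dates are parsed as ISO dates and
#' lengths validated as positive. When `gm` is supplied, individuals absent
#' from the genotype matrix are retained but flagged in `in_genotypes`.
#'
#' @param tsv_path path to the TSV file.
#' @param gm optional `genotype_matrix` used to flag unknown individuals.
#' @return data.frame of typed records, one per row of the file.
#' @export
read_metadata <- function(tsv_path, gm = NULL) {
  md <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  req <- c("individual_id", "location", "capture_date", "total_length_mm",
           "species")
  miss <- setdiff(req, names(md))
  if (length(miss))
    stop("metadata lacks required column(s): ", paste(miss, collapse = ", "))
  md$capture_date <- as.Date(md$capture_date)
  if (anyNA(md$capture_date)) stop("unparseable capture_date in ", tsv_path)
  md$total_length_mm <- as.numeric(md$total_length_mm)
  if (any(!is.finite(md$total_length_mm) | md$total_length_mm <= 0))
    stop("total_length_mm must be positive")
  if (anyDuplicated(md$individual_id))
    stop("duplicate individual_id in ", tsv_path)
  if (!is.null(gm)) {
    md$in_genotypes <- md$individual_id %in% gm$individual_ids
    if (any(!md$in_genotypes))
      log_msg(sum(!md$in_genotypes),
              " metadata individual(s) not in the genotype matrix")
  }
  md
}

#' Write a sample metadata table
#'
#' @param metadata data.frame as returned by [read_metadata()].
#' @param tsv_path output path.
#' @return `tsv_path`, invisibly.
#' @export
write_metadata <- function(metadata, tsv_path) {
  utils::write.table(metadata, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tsv_path)
}
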