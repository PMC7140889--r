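#' Column-name mapping for summary-statistics files
#'
#' Describes which columns of a tab-separated GWAS summary-statistics file
#' hold each required field. The defaults follow the common PLINK-style
#' convention (`SNP`, `CHR`, `BP`, `A1`, `A2`, `BETA`, `SE`, `P`, `N`, `FRQ`).
#' `n` and `eaf` are optional: set them to `NA` if the file has no such
#' column.
#'
#' @param snp_id,chrom,pos,effect_allele,other_allele,beta,se,pvalue,n,eaf
#'   Column names in the file.
#' @return A named character vector usable as the `dialect` argument of
#'   [read_sumstats()].
#' @export
sumstats_dialect <- function(snp_id = "SNP", chrom = "CHR", pos = "BP",
                             effect_allele = "A1", other_allele = "A2",
                             beta = "BETA", se = "SE", pvalue = "P",
                             n = "N", eaf = "FRQ") {
  c(snp_id = snp_id, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    beta = beta, se = se, pvalue = pvalue, n = n, eaf = eaf)
}

#' Read GWAS summary statistics
#'
#' Reads a tab-separated (optionally gzipped) summary-statistics table,
#' renames columns according to `dialect`, and validates rows with
#' [validate_sumstats()]. Rows violating the invariants (blank or duplicated
#' variant IDs, identical or non-ACGT alleles, non-positive standard error,
#' p-value outside (0, 1], non-finite effect) are dropped with a warning.
#'
#' @param path Path to the file.
#' @param dialect Column mapping from [sumstats_dialect()].
#' @param zero_based Set `TRUE` if positions in the file are 0-based
#'   (BED dialect); they are converted to the 1-based convention used
#'   throughout the package.
#' @return A tibble with columns `snp_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pvalue`, and, when present in the file,
#'   `n` and `eaf`.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(),
                          zero_based = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("Summary-statistics file not found: '%s'.", path))
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- dialect[c("snp_id", "chrom", "pos", "effect_allele",
                        "other_allele", "beta", "se", "pvalue")]
  missing <- setdiff(unname(required), names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Mapped column(s) absent from '%s': %s.",
                  path, paste(missing, collapse = ", ")))
  }
  present <- dialect[!is.na(dialect) & dialect %in% names(raw)]
  out <- raw[, unname(present)]
  names(out) <- names(present)
  out <- as_tibble(out)
  out$chrom <- as.character(out$chrom)
  if (zero_based) out$pos <- out$pos + 1L
  validate_sumstats(out)
}

#' Validate a summary-statistics table
#'
#' Enforces the per-row invariants of a summary-statistics table and drops
#' offending rows with a warning naming each count. Alleles are upper-cased.
#'
#' @param x A data frame with at least `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pvalue` columns.
#' @return The validated tibble.
#' @export
validate_sumstats <- function(x) {
  x <- as_tibble(x)
  x$effect_allele <- toupper(x$effect_allele)
  x$other_allele <- toupper(x$other_allele)
  drops <- c(
    missing_id = sum(is.na(x$snp_id) | x$snp_id == ""),
    bad_alleles = 0L, bad_se = 0L, bad_p = 0L, bad_beta = 0L,
    duplicate_id = 0L
  )
  keep <- !is.na(x$snp_id) & x$snp_id != ""
  x <- x[keep, ]
  ok_allele <- x$effect_allele %in% BASES & x$other_allele %in% BASES &
    x$effect_allele != x$other_allele
  drops["bad_alleles"] <- sum(!ok_allele)
  x <- x[ok_allele, ]
  ok_se <- is.finite(x$se) & x$se > 0
  drops["bad_se"] <- sum(!ok_se)
  x <- x[ok_se, ]
  ok_p <- is.finite(x$pvalue) & x$pvalue > 0 & x$pvalue <= 1
  drops["bad_p"] <- sum(!ok_p)
  x <- x[ok_p, ]
  ok_beta <- is.finite(x$beta)
  drops["bad_beta"] <- sum(!ok_beta)
  x <- x[ok_beta, ]
  dup <- duplicated(x$snp_id)
  drops["duplicate_id"] <- sum(dup)
  x <- x[!dup, ]
  if (nrow(x) == 0L) {
    abort("No valid summary-statistics rows remain after validation.")
  }
  if (any(drops > 0)) {
    msg <- paste(sprintf("%s: %d", names(drops)[drops > 0], drops[drops > 0]),
                 collapse = ", ")
    warn(sprintf("Dropped %d invalid summary-statistics row(s) (%s).",
                 sum(drops), msg))
  }
  x
}

#' Write summary statistics to a tab-separated file
#'
#' @param x A summary-statistics tibble.
#' @param path Output path (a `.gz` suffix triggers gzip compression).
#' @param dialect Column names to use in the file, from [sumstats_dialect()].
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path, dialect = sumstats_dialect()) {
  out <- x
  present <- intersect(names(dialect), names(out))
  out <- out[, present]
  names(out) <- unname(dialect[present])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
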