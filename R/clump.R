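#' P-value informed LD clumping
#'
#' Greedy selection of independent SNPs: candidates are visited in ascending
#' order of the chosen p-value (ties broken by chromosome, position, then SNP
#' ID for determinism) and a SNP is retained iff its squared correlation with
#' every already-retained SNP is below `r2_max`. Correlations come from the
#' block-diagonal LD reference, so only SNPs in the same block can exclude
#' one another; SNPs absent from the reference are treated as independent
#' singleton blocks (counted and reported).
#'
#' @param pair A `harmonized_pair` tibble (or any tibble with `snp_id`,
#'   `chrom`, `pos` and the p-value column).
#' @param ld An `ld_ref` object.
#' @param r2_max Exclusion threshold in (0, 1] (default 0.1).
#' @param p_col Column holding the prioritising p-value (default `"p_1"`,
#'   i.e. dataset 1 drives the selection).
#' @return Character vector of retained (index) SNP IDs, in selection order.
#' @export
clump_snps <- function(pair, ld, r2_max = 0.1, p_col = "p_1") {
  check_number(r2_max, "r2_max", lower = 0, upper = 1, closed_lower = FALSE)
  if (!p_col %in% names(pair)) {
    abort(sprintf("Column '%s' not found.", p_col))
  }
  ord <- order(pair[[p_col]], pair$chrom, pair$pos, pair$snp_id)
  ids <- pair$snp_id[ord]
  hit <- match(ids, ld$index$snp_id)
  n_missing <- sum(is.na(hit))
  if (n_missing > 0) {
    inform(sprintf(
      "%d SNP(s) absent from the LD reference; treated as singleton blocks.",
      n_missing))
  }
  block <- ld$index$block[hit]
  idx <- ld$index$idx[hit]
  retained <- logical(length(ids))
  kept_by_block <- vector("list", length(ld$blocks))
  for (i in seq_along(ids)) {
    b <- block[i]
    if (is.na(b)) {
      retained[i] <- TRUE
      next
    }
    prev <- kept_by_block[[b]]
    if (length(prev) == 0L) {
      retained[i] <- TRUE
      kept_by_block[[b]] <- idx[i]
    } else {
      r2 <- ld$blocks[[b]]$r[prev, idx[i]]^2
      if (all(r2 < r2_max)) {
        retained[i] <- TRUE
        kept_by_block[[b]] <- c(prev, idx[i])
      }
    }
  }
  ids[retained]
}
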