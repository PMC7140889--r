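#' Harmonize two summary-statistics tables to a shared effect allele
#'
#' Intersects the two tables on `snp_id` and aligns the second trait's
#' effects to the first trait's effect allele. Where the second table codes
#' the same allele pair in swapped order, its effect sign is flipped and its
#' effect-allele frequency complemented; allele pairs that match only after
#' strand complementation are resolved the same way. Palindromic SNPs
#' (A/T, C/G), whose strand cannot be resolved from the alleles alone, are
#' dropped by default, or resolved from allele frequencies when
#' `resolve_palindromic = TRUE` and both frequencies are sufficiently far
#' from 0.5. Irreconcilable allele pairs are dropped and counted, never
#' silently kept.
#'
#' @param a,b Validated summary-statistics tibbles (see [read_sumstats()]).
#' @param drop_palindromic Drop palindromic SNPs (default `TRUE`).
#' @param resolve_palindromic Attempt frequency-based orientation of
#'   palindromic SNPs instead of dropping them; requires `eaf` in both
#'   tables. Ignored when `drop_palindromic = TRUE`.
#' @param eaf_margin Minimum distance of both frequencies from 0.5 for a
#'   palindromic SNP to be considered resolvable (default 0.08).
#' @return A tibble of class `harmonized_pair` keyed by `snp_id`, with the
#'   first trait's coordinates and alleles and columns `beta_1`, `se_1`,
#'   `p_1`, `n_1`, `eaf_1` and `beta_2`, `se_2`, `p_2`, `n_2`, `eaf_2`
#'   (where available). The attribute `harmonization` records the counts of
#'   kept, flipped and dropped records.
#' @export
harmonize_pair <- function(a, b, drop_palindromic = TRUE,
                           resolve_palindromic = FALSE, eaf_margin = 0.08) {
  keep_cols <- function(x, suffix) {
    cols <- intersect(c("beta", "se", "pvalue", "n", "eaf"), names(x))
    out <- x[, c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                 cols)]
    ren <- c(beta = "beta", se = "se", pvalue = "p", n = "n", eaf = "eaf")
    names(out)[match(cols, names(out))] <-
      paste0(ren[cols], "_", suffix)
    out
  }
  xa <- keep_cols(a, "1")
  xb <- keep_cols(b, "2")
  names(xb)[2:5] <- c("chrom_b", "pos_b", "ea_b", "oa_b")
  m <- inner_join(xa, xb, by = "snp_id")
  n_intersect <- nrow(m)
  if (n_intersect == 0L) {
    abort("The two tables share no SNP IDs.")
  }

  ea <- m$effect_allele
  oa <- m$other_allele
  eb <- m$ea_b
  ob <- m$oa_b
  same <- eb == ea & ob == oa
  swap <- eb == oa & ob == ea
  csame <- complement_alleles(eb) == ea & complement_alleles(ob) == oa
  cswap <- complement_alleles(eb) == oa & complement_alleles(ob) == ea
  pal <- is_palindromic(ea, oa)

  # orientation: +1 keep, -1 flip, 0 irreconcilable
  orient <- ifelse(same | (!same & !swap & csame), 1L,
                   ifelse(swap | cswap, -1L, 0L))
  status <- rep("kept", n_intersect)
  status[orient == 0L] <- "mismatch"

  if (any(pal) && drop_palindromic) {
    status[pal & status != "mismatch"] <- "palindromic"
  } else if (any(pal) && resolve_palindromic) {
    if (!all(c("eaf_1", "eaf_2") %in% names(m))) {
      abort("Frequency-based palindromic resolution requires `eaf` in both tables.")
    }
    # for palindromic SNPs allele labels cannot distinguish strand; use
    # frequency agreement: matching minor/major side implies same allele
    f1 <- m$eaf_1
    f2 <- m$eaf_2
    inform_ok <- pal & !is.na(f1) & !is.na(f2) &
      abs(f1 - 0.5) > eaf_margin & abs(f2 - 0.5) > eaf_margin
    status[pal & !inform_ok & status != "mismatch"] <- "palindromic"
    flip_freq <- (f1 > 0.5) != (f2 > 0.5)
    orient[inform_ok] <- ifelse(flip_freq[inform_ok], -1L, 1L)
  }

  kept <- status == "kept"
  out <- m[kept, ]
  flip <- orient[kept] == -1L
  out$beta_2 <- ifelse(flip, -out$beta_2, out$beta_2)
  if ("eaf_2" %in% names(out)) {
    out$eaf_2 <- ifelse(flip, 1 - out$eaf_2, out$eaf_2)
  }
  out$ea_b <- NULL; out$oa_b <- NULL; out$chrom_b <- NULL; out$pos_b <- NULL
  counts <- list(
    n_intersect = n_intersect,
    n_kept = sum(kept),
    n_flipped = sum(flip),
    n_dropped_mismatch = sum(status == "mismatch"),
    n_dropped_palindromic = sum(status == "palindromic"))
  if (counts$n_kept == 0L) {
    abort("No SNPs remain after harmonization.")
  }
  inform(sprintf(
    "Harmonized %d shared SNP(s): %d kept (%d flipped), %d palindromic and %d mismatched dropped.",
    counts$n_intersect, counts$n_kept, counts$n_flipped,
    counts$n_dropped_palindromic, counts$n_dropped_mismatch))
  structure(out, harmonization = counts,
            class = c("harmonized_pair", class(out)))
}

#' @export
print.harmonized_pair <- function(x, ...) {
  h <- attr(x, "harmonization")
  cat(sprintf(
    "<harmonized_pair> %d SNPs (of %d shared; %d flipped, %d dropped)\n",
    h$n_kept, h$n_intersect, h$n_flipped,
    h$n_dropped_mismatch + h$n_dropped_palindromic))
  NextMethod()
}
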