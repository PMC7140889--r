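#' The 12 fixed p-value cutpoints of the concordance grid
#' @export
seca_thresholds <- c(0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8,
                     0.9, 1.0)

# internal: per-SNP threshold bin (smallest cutoff index with p <= cutoff)
# and the 4 cumulative 12x12 sign-category count matrices.
# cat 1: beta1>0 & beta2>0, 2: +/-, 3: -/+, 4: -/-
seca_counts <- function(p1, p2, s1, s2) {
  nt <- length(seca_thresholds)
  b1 <- nt + 1L - findInterval(-p1, rev(-seca_thresholds))
  b2 <- nt + 1L - findInterval(-p2, rev(-seca_thresholds))
  cat <- 1L + (s2 < 0) + 2L * (s1 < 0)
  idx <- b1 + nt * (b2 - 1L) + nt * nt * (cat - 1L)
  counts <- tabulate(idx, nbins = 4L * nt * nt)
  arr <- array(counts, dim = c(nt, nt, 4L))
  for (k in 1:4) {
    arr[, , k] <- apply(apply(arr[, , k], 2, cumsum), 1, cumsum)
    # after the double cumsum rows/cols are transposed back
    arr[, , k] <- t(arr[, , k])
  }
  arr
}

# wait-free helper: given cumulative category array, the grid summaries
seca_grid_from_counts <- function(arr) {
  n_conc <- arr[, , 1] + arr[, , 4]
  n_disc <- arr[, , 2] + arr[, , 3]
  list(pp = arr[, , 1], pm = arr[, , 2], mp = arr[, , 3], mm = arr[, , 4],
       n_conc = n_conc, n_disc = n_disc, n = n_conc + n_disc)
}

seca_extract <- function(pair, independent_snps) {
  sub <- pair[pair$snp_id %in% independent_snps, ]
  zero <- sub$beta_1 == 0 | sub$beta_2 == 0
  if (any(zero)) {
    inform(sprintf(
      "Excluded %d SNP(s) with a zero effect from concordance counting.",
      sum(zero)))
    sub <- sub[!zero, ]
  }
  if (nrow(sub) == 0L) {
    abort("No independent SNPs with defined effect signs.")
  }
  sub
}

#' Build the 12x12 SNP-effect concordance grid
#'
#' Restricts a harmonized pair to the supplied independent (clumped) SNPs
#' and cross-tabulates the two traits' effect directions within every
#' combination of the 12 nested p-value subsets (`P1 <= cutoff1`,
#' `P2 <= cutoff2`), yielding 144 cells. SNPs with an effect of exactly zero
#' in either trait are excluded from concordance counting and reported.
#'
#' @param pair A `harmonized_pair` tibble.
#' @param independent_snps Character vector of clumped SNP IDs (see
#'   [clump_snps()]).
#' @return A tibble of class `seca_grid` with one row per cell: `p1_cutoff`,
#'   `p2_cutoff`, `n_concordant`, `n_discordant`, `n_snps`,
#'   `prop_concordant`. The underlying per-SNP data are carried in the
#'   `seca_data` attribute for the test and permutation stages.
#' @export
build_grid <- function(pair, independent_snps) {
  if (length(independent_snps) == 0L) {
    abort("`independent_snps` is empty.")
  }
  sub <- seca_extract(pair, independent_snps)
  arr <- seca_counts(sub$p_1, sub$p_2, sign(sub$beta_1), sign(sub$beta_2))
  g <- seca_grid_from_counts(arr)
  nt <- length(seca_thresholds)
  cells <- tibble(
    p1_cutoff = rep(seca_thresholds, times = nt),
    p2_cutoff = rep(seca_thresholds, each = nt),
    n_concordant = as.vector(g$n_conc),
    n_discordant = as.vector(g$n_disc),
    n_snps = as.vector(g$n))
  cells$prop_concordant <- ifelse(cells$n_snps > 0,
                                  cells$n_concordant / cells$n_snps,
                                  NA_real_)
  structure(cells,
            seca_data = sub[, c("snp_id", "p_1", "p_2", "beta_1", "beta_2")],
            class = c("seca_grid", class(cells)))
}

# Fisher tests for all 144 cells from the category matrices
seca_fisher <- function(g) {
  nt <- length(seca_thresholds)
  or <- p <- rep(NA_real_, nt * nt)
  for (i in seq_len(nt * nt)) {
    ft <- fisher_exact_2x2(g$pp[i], g$pm[i], g$mp[i], g$mm[i])
    or[i] <- ft$or
    p[i] <- ft$p
  }
  list(or = or, p = p)
}

#' Fisher exact concordance tests over a SECA grid
#'
#' For each cell, forms the 2x2 table of (trait-1 sign up/down) x (trait-2
#' sign up/down) among the cell's SNPs and attaches the sample odds ratio
#' `or_ft` and the two-sided conditional exact p-value `p_ft` (see
#' [fisher_exact_2x2()]). Cells with a degenerate margin get `or_ft = NA`
#' and `p_ft = 1`; empty cells get `NA` for both.
#'
#' @param grid A `seca_grid` from [build_grid()].
#' @return The grid with `or_ft` and `p_ft` columns added.
#' @export
concordance_test <- function(grid) {
  sub <- attr(grid, "seca_data")
  arr <- seca_counts(sub$p_1, sub$p_2, sign(sub$beta_1), sign(sub$beta_2))
  g <- seca_grid_from_counts(arr)
  ft <- seca_fisher(g)
  grid$or_ft <- ft$or
  grid$p_ft <- ft$p
  grid$p_ft[grid$n_snps == 0] <- NA_real_
  grid
}

#' Binomial test for an excess of significantly concordant subsets
#'
#' Counts grid cells whose Fisher test is both nominally significant
#' (`p_ft <= alpha`) and in the concordant direction (`or_ft > 1`), and
#' compares the count with the one-sided tail of `Binomial(144, p0)`. The
#' default null cell probability `p0 = alpha / 2 = 0.025` is the chance of a
#' cell being simultaneously significant and concordant under sign symmetry;
#' the permutation p-value from [permutation_null()] is the primary
#' inferential output.
#'
#' @param grid A tested `seca_grid` (after [concordance_test()]).
#' @param alpha Per-cell significance level (default 0.05).
#' @param p0 Null probability per cell (default `alpha / 2`).
#' @return A list with `n_sig_subsets`, `n_cells` and the one-sided tail
#'   `p_binomial = P(X >= n_sig_subsets)`.
#' @export
binomial_subset_test <- function(grid, alpha = 0.05, p0 = alpha / 2) {
  if (!"p_ft" %in% names(grid)) {
    abort("Run `concordance_test()` before `binomial_subset_test()`.")
  }
  n_cells <- nrow(grid)
  n_sig <- sum(grid$or_ft > 1 & grid$p_ft <= alpha, na.rm = TRUE)
  list(n_sig_subsets = n_sig, n_cells = n_cells,
       p_binomial = stats::pbinom(n_sig - 1, n_cells, p0,
                                  lower.tail = FALSE))
}

# single permutation/observed summary: number of significant concordant
# cells and the minimum cell p
seca_summary_stats <- function(p1, p2, s1, s2, alpha = 0.05) {
  arr <- seca_counts(p1, p2, s1, s2)
  g <- seca_grid_from_counts(arr)
  ft <- seca_fisher(g)
  ok <- as.vector(g$n) > 0
  list(n_sig = sum(ft$or > 1 & ft$p <= alpha, na.rm = TRUE),
       min_p = if (any(ok)) min(ft$p[ok], na.rm = TRUE) else 1)
}

#' Permutation null for the SECA summary statistics
#'
#' Each permutation independently flips the sign of dataset 2's effect for
#' every SNP with a fair coin (p-values, and hence subset membership, are
#' preserved; dataset 1 conditioning defines the subsets), rebuilds the
#' grid, and recomputes the number of significant concordant subsets and the
#' minimum cell p-value. Empirical p-values use the add-one formula
#' `(1 + #more extreme) / (n_perm + 1)`, so they are never smaller than
#' `1 / (n_perm + 1)`; a Clopper-Pearson 95% CI is attached to the
#' subset-count p.
#'
#' @param pair A `harmonized_pair`.
#' @param independent_snps Clumped SNP IDs.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer RNG seed.
#' @param alpha Per-cell significance level (default 0.05).
#' @return A list with `p_fsig_permuted`, its `ci` (95% Clopper-Pearson),
#'   `p_ftmin_permuted`, and the observed summaries `n_sig_subsets` and
#'   `min_p_ft`.
#' @export
permutation_null <- function(pair, independent_snps, n_perm = 1000, seed,
                             alpha = 0.05) {
  if (n_perm < 1) abort("`n_perm` must be at least 1.")
  sub <- seca_extract(pair, independent_snps)
  s1 <- sign(sub$beta_1)
  s2 <- sign(sub$beta_2)
  obs <- seca_summary_stats(sub$p_1, sub$p_2, s1, s2, alpha)
  set.seed(seed)
  m <- nrow(sub)
  perm_nsig <- integer(n_perm)
  perm_minp <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    flip <- sample(c(-1, 1), m, replace = TRUE)
    st <- seca_summary_stats(sub$p_1, sub$p_2, s1, s2 * flip, alpha)
    perm_nsig[b] <- st$n_sig
    perm_minp[b] <- st$min_p
  }
  x_sig <- sum(perm_nsig >= obs$n_sig)
  x_min <- sum(perm_minp <= obs$min_p)
  p_fsig <- (1 + x_sig) / (n_perm + 1)
  p_ftmin <- (1 + x_min) / (n_perm + 1)
  list(p_fsig_permuted = p_fsig,
       ci = clopper_pearson(x_sig + 1, n_perm + 1),
       p_ftmin_permuted = p_ftmin,
       n_sig_subsets = obs$n_sig,
       min_p_ft = obs$min_p,
       n_perm = n_perm)
}

#' SNP-effect concordance analysis (SECA)
#'
#' End-to-end convenience wrapper: p-value-informed clumping of the
#' harmonized pair, construction of the 144-cell concordance grid, Fisher
#' exact tests per cell, the binomial excess-subset test and the permutation
#' null.
#'
#' @inheritParams permutation_null
#' @param ld An `ld_ref`.
#' @param r2_max Clumping threshold (default 0.1).
#' @return A list of class `seca_result` with elements `cells` (the tested
#'   grid), `binomial`, `permutation` and `n_independent`.
#' @export
seca <- function(pair, ld, r2_max = 0.1, n_perm = 1000, seed,
                 alpha = 0.05) {
  snps <- clump_snps(pair, ld, r2_max = r2_max)
  grid <- concordance_test(build_grid(pair, snps))
  res <- list(cells = grid,
              binomial = binomial_subset_test(grid, alpha = alpha),
              permutation = permutation_null(pair, snps, n_perm = n_perm,
                                             seed = seed, alpha = alpha),
              n_independent = length(snps))
  class(res) <- "seca_result"
  res
}

#' @export
print.seca_result <- function(x, ...) {
  full <- x$cells[x$cells$p1_cutoff == 1 & x$cells$p2_cutoff == 1, ]
  cat(sprintf("<seca_result> %d independent SNPs\n", x$n_independent))
  cat(sprintf("  (1, 1) cell: %d/%d concordant (%.2f), OR = %.2f, p = %.3g\n",
              full$n_concordant, full$n_snps, full$prop_concordant,
              full$or_ft, full$p_ft))
  cat(sprintf("  significant concordant subsets: %d of %d (binomial p = %.3g)\n",
              x$binomial$n_sig_subsets, x$binomial$n_cells,
              x$binomial$p_binomial))
  cat(sprintf("  permutation: P_Fsig = %.3g (95%% CI %.3g-%.3g), P_FTmin = %.3g\n",
              x$permutation$p_fsig_permuted, x$permutation$ci[1],
              x$permutation$ci[2], x$permutation$p_ftmin_permuted))
  invisible(x)
}
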