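#' Per-SNP LD scores from a block-diagonal reference
#'
#' The LD score of SNP j is the sum of squared correlations between j and
#' every SNP in its block (including itself), so scores are always >= 1.
#'
#' @param ld An `ld_ref` object.
#' @return A tibble with columns `snp_id`, `ldscore`.
#' @export
compute_ld_scores <- function(ld) {
  scores <- unlist(lapply(ld$blocks, function(b) rowSums(b$r^2)),
                   use.names = FALSE)
  tibble(snp_id = ld$index$snp_id, ldscore = scores)
}

# merge sumstats with ld scores, compute chi2, apply the standard cap filter
ldsc_prepare <- function(stats, ldscores, m = NULL) {
  d <- inner_join(stats, ldscores, by = "snp_id")
  d <- d[order(d$chrom, d$pos), ]
  if (nrow(d) < 200) {
    abort("LD score regression needs at least 200 SNPs with matched LD scores.")
  }
  if (!"n" %in% names(d)) abort("Summary statistics must carry `n`.")
  d$z <- d$beta / d$se
  d$chisq <- d$z^2
  cap <- max(80, 0.001 * stats::median(d$n))
  n_cap <- sum(d$chisq > cap)
  if (n_cap > 0) {
    inform(sprintf("Removed %d SNP(s) with chi-square above %.1f.",
                   n_cap, cap))
    d <- d[d$chisq <= cap, ]
  }
  attr(d, "m") <- if (is.null(m)) nrow(d) else m
  d
}

# core single-trait regression: chi2 ~ n*l/m, optionally with a fixed
# intercept; returns slope (= h2 observed) with jackknife se
ldsc_regress <- function(d, m, constrain_intercept = NULL, n_blocks = 200) {
  x <- d$n * d$ldscore / m
  y <- d$chisq
  # heteroscedasticity weights from an unweighted pre-fit
  pre <- stats::lm.fit(cbind(1, x), y)$coefficients[2]
  h2_prior <- min(1, max(0, pre))
  w <- 1 / (d$ldscore * (1 + d$n * h2_prior * d$ldscore / m)^2)
  blocks <- jackknife_blocks(nrow(d), n_blocks)
  if (max(blocks) < n_blocks) {
    warn(sprintf("Jackknife blocks reduced to %d for %d SNPs.",
                 max(blocks), nrow(d)))
  }
  if (is.null(constrain_intercept)) {
    fit <- wls_jackknife(cbind(intercept = 1, slope = x), y, w, blocks)
    list(h2_obs = fit$est[2], h2_se = fit$se[2],
         intercept = fit$est[1], intercept_se = fit$se[1],
         constrained = FALSE, loo = fit$loo[, 2], blocks = blocks,
         weights = w)
  } else {
    fit <- wls_jackknife(cbind(slope = x), y - constrain_intercept, w,
                         blocks)
    list(h2_obs = fit$est[1], h2_se = fit$se[1],
         intercept = constrain_intercept, intercept_se = NA_real_,
         constrained = TRUE, loo = fit$loo[, 1], blocks = blocks,
         weights = w)
  }
}

#' Estimate SNP heritability by LD score regression
#'
#' Regresses per-SNP association chi-square statistics on `n * l / m`
#' (sample size times LD score over SNP count): under a polygenic model the
#' slope estimates the observed-scale SNP heritability and the intercept
#' captures confounding inflation. Weights correct for heteroscedasticity
#' using a slope from an unweighted pre-fit; standard errors come from a
#' delete-a-block jackknife over contiguous SNP blocks. SNPs with
#' chi-square above `max(80, 0.001 n)` are removed before fitting.
#'
#' @param stats A summary-statistics tibble with `n`.
#' @param ldscores Tibble from [compute_ld_scores()].
#' @param constrain_intercept Fix the regression intercept to this value
#'   (e.g. 1 when no confounding inflation is assumed); `NULL` (default)
#'   estimates it.
#' @param sample_prev,pop_prev Optional sample and population prevalences
#'   for a case-control trait; when both are given the heritability is also
#'   reported on the liability scale with a symmetric 95% CI.
#' @param n_blocks Number of jackknife blocks (default 200; reduced with a
#'   warning when there are too few SNPs).
#' @param m Number of SNPs used as the polygenicity denominator (defaults
#'   to the number of regression SNPs).
#' @return An object of class `ldsc_fit` (see [tidy.ldsc_fit()]).
#' @export
fit_h2 <- function(stats, ldscores, constrain_intercept = NULL,
                   sample_prev = NULL, pop_prev = NULL, n_blocks = 200,
                   m = NULL) {
  d <- ldsc_prepare(stats, ldscores, m)
  m_eff <- attr(d, "m")
  reg <- ldsc_regress(d, m_eff, constrain_intercept, n_blocks)
  out <- list(type = "h2", h2_obs = unname(reg$h2_obs),
              h2_se = unname(reg$h2_se),
              intercept = unname(reg$intercept),
              intercept_se = unname(reg$intercept_se),
              intercept_constrained = reg$constrained,
              n_snps_used = nrow(d), m = m_eff,
              jackknife_blocks = max(reg$blocks))
  if (!is.null(sample_prev) && !is.null(pop_prev)) {
    f <- liability_factor(sample_prev, pop_prev)
    out$h2_liab <- out$h2_obs * f
    out$h2_liab_se <- out$h2_se * f
    out$h2_liab_ci <- out$h2_liab + c(-1, 1) * 1.96 * out$h2_liab_se
    out$sample_prev <- sample_prev
    out$pop_prev <- pop_prev
  }
  structure(out, class = "ldsc_fit")
}

#' Observed-to-liability scale conversion factor
#'
#' For a binary trait analysed as case-control, converts observed-scale
#' heritability to the liability scale:
#' `h2_liab = h2_obs * K^2 (1-K)^2 / (Ks (1-Ks) phi(z)^2)` where `K` is the
#' population prevalence, `Ks` the sample prevalence, `z` the standard
#' normal quantile at `1 - K` and `phi` the standard normal density.
#'
#' @param sample_prev Sample prevalence `Ks` in (0, 1).
#' @param pop_prev Population prevalence `K` in (0, 1).
#' @return The multiplicative conversion factor.
#' @export
liability_factor <- function(sample_prev, pop_prev) {
  check_number(sample_prev, "sample_prev", 0, 1, FALSE, FALSE)
  check_number(pop_prev, "pop_prev", 0, 1, FALSE, FALSE)
  K <- pop_prev
  Ks <- sample_prev
  z <- stats::qnorm(1 - K)
  K^2 * (1 - K)^2 / (Ks * (1 - Ks) * stats::dnorm(z)^2)
}

#' Convert an observed-scale heritability to the liability scale
#'
#' @param h2_obs Observed-scale heritability.
#' @inheritParams liability_factor
#' @return Liability-scale heritability.
#' @export
obs_to_liability <- function(h2_obs, sample_prev, pop_prev) {
  h2_obs * liability_factor(sample_prev, pop_prev)
}

#' Cross-trait genetic correlation by bivariate LD score regression
#'
#' Regresses the per-SNP z-score product on `sqrt(n1 n2) * l / m`: the slope
#' estimates the genetic covariance, and the genetic correlation is
#' `rg = gencov / sqrt(h2_1 h2_2)` with the per-trait heritabilities fitted
#' under the given intercept constraints. The standard error and p-value of
#' `rg` come from a joint delete-a-block jackknife over the three
#' regressions; the genetic covariance intercept (nonzero only under sample
#' overlap) can be constrained to zero.
#'
#' @param s1,s2 Summary-statistics tibbles with aligned effect alleles
#'   (harmonize first if in doubt).
#' @param ldscores Tibble from [compute_ld_scores()].
#' @param constrain_i1,constrain_i2 Optional fixed intercepts for the two
#'   univariate regressions (`NULL` estimates them).
#' @param constrain_gencov If `TRUE` (use when the samples do not overlap),
#'   the genetic covariance intercept is fixed at zero.
#' @param n_blocks Number of jackknife blocks.
#' @param m Polygenicity denominator (defaults to the number of shared
#'   regression SNPs).
#' @return An object of class `ldsc_fit` carrying `rg`, `rg_se`, `rg_p`,
#'   the genetic covariance slope and both univariate fits.
#' @export
fit_rg <- function(s1, s2, ldscores, constrain_i1 = NULL,
                   constrain_i2 = NULL, constrain_gencov = FALSE,
                   n_blocks = 200, m = NULL) {
  shared <- intersect(s1$snp_id, s2$snp_id)
  if (length(shared) < 200) {
    abort("Bivariate LD score regression needs >= 200 shared SNPs.")
  }
  d1 <- ldsc_prepare(s1[s1$snp_id %in% shared, ], ldscores, m)
  d2 <- ldsc_prepare(s2[s2$snp_id %in% shared, ], ldscores, m)
  common <- intersect(d1$snp_id, d2$snp_id)
  d1 <- d1[match(common, d1$snp_id), ]
  d2 <- d2[match(common, d2$snp_id), ]
  m_eff <- if (is.null(m)) length(common) else m
  n_snp <- length(common)

  r1 <- ldsc_regress(d1, m_eff, constrain_i1, n_blocks)
  r2 <- ldsc_regress(d2, m_eff, constrain_i2, n_blocks)
  h2_1 <- unname(r1$h2_obs)
  h2_2 <- unname(r2$h2_obs)

  l <- d1$ldscore
  x <- sqrt(d1$n * d2$n) * l / m_eff
  y <- d1$z * d2$z
  # pre-fit for covariance weights
  pre <- stats::lm.fit(cbind(1, x), y)$coefficients[2]
  rho_prior <- pre
  v1 <- 1 + d1$n * max(0, h2_1) * l / m_eff
  v2 <- 1 + d2$n * max(0, h2_2) * l / m_eff
  w <- 1 / (l * (v1 * v2 + (sqrt(d1$n * d2$n) * rho_prior * l / m_eff)^2))
  blocks <- jackknife_blocks(n_snp, n_blocks)

  if (constrain_gencov) {
    cov_fit <- wls_jackknife(cbind(slope = x), y, w, blocks)
    gencov <- cov_fit$est[1]
    gencov_loo <- cov_fit$loo[, 1]
    gencov_int <- 0
    gencov_int_se <- NA_real_
  } else {
    cov_fit <- wls_jackknife(cbind(intercept = 1, slope = x), y, w, blocks)
    gencov <- cov_fit$est[2]
    gencov_loo <- cov_fit$loo[, 2]
    gencov_int <- cov_fit$est[1]
    gencov_int_se <- cov_fit$se[1]
  }

  out <- list(type = "rg", gencov = unname(gencov),
              gencov_intercept = unname(gencov_int),
              gencov_intercept_se = unname(gencov_int_se),
              gencov_constrained = constrain_gencov,
              h2_1 = h2_1, h2_2 = h2_2,
              intercept_1 = unname(r1$intercept),
              intercept_2 = unname(r2$intercept),
              n_snps_used = n_snp, m = m_eff,
              jackknife_blocks = max(blocks))
  if (h2_1 <= 0 || h2_2 <= 0) {
    warn("Non-positive heritability estimate; genetic correlation undefined.")
    out$rg <- NA_real_
    out$rg_se <- NA_real_
    out$rg_p <- NA_real_
    return(structure(out, class = "ldsc_fit"))
  }
  rg_hat <- gencov / sqrt(h2_1 * h2_2)
  # joint jackknife: recompute the ratio with each block deleted
  g <- max(blocks)
  rg_loo <- numeric(g)
  for (b in seq_len(g)) {
    h1b <- r1$loo[b]
    h2b <- r2$loo[b]
    rg_loo[b] <- if (h1b > 0 && h2b > 0) {
      gencov_loo[b] / sqrt(h1b * h2b)
    } else NA_real_
  }
  ok <- is.finite(rg_loo)
  pseudo <- g * rg_hat - (g - 1) * rg_loo[ok]
  rg_se <- sqrt(stats::var(pseudo) / sum(ok))
  out$rg <- unname(rg_hat)
  out$rg_se <- unname(rg_se)
  out$rg_p <- two_sided_p(rg_hat / rg_se)
  structure(out, class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  if (x$type == "h2") {
    cat(sprintf("<ldsc_fit: h2> observed h2 = %.4f (se %.4f), intercept = %.4f%s\n",
                x$h2_obs, x$h2_se, x$intercept,
                if (x$intercept_constrained) " (constrained)" else
                  sprintf(" (se %.4f)", x$intercept_se)))
    if (!is.null(x$h2_liab)) {
      cat(sprintf("  liability-scale h2 = %.2f%% (95%% CI %.2f-%.2f%%)\n",
                  100 * x$h2_liab, 100 * x$h2_liab_ci[1],
                  100 * x$h2_liab_ci[2]))
    }
  } else {
    cat(sprintf("<ldsc_fit: rg> rg = %.4f (se %.4f, p = %.3g); gencov intercept %s\n",
                x$rg, x$rg_se, x$rg_p,
                if (x$gencov_constrained) "constrained to 0" else
                  sprintf("%.4f", x$gencov_intercept)))
  }
  cat(sprintf("  %d SNPs, %d jackknife blocks\n", x$n_snps_used,
              x$jackknife_blocks))
  invisible(x)
}
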