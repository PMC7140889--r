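#' Inverse-variance-weighted fixed-effect meta-analysis of two estimates
#'
#' Vectorised over SNPs: `beta_fe = sum(w_i b_i) / sum(w_i)` with
#' `w_i = 1 / se_i^2`, `se_fe = 1 / sqrt(sum(w_i))`, two-sided normal
#' p-value.
#'
#' @param b1,se1,b2,se2 Numeric vectors of study effects and standard
#'   errors (ses must be positive).
#' @return A tibble with columns `beta_fe`, `se_fe`, `p_fe`.
#' @export
fixed_effect_meta <- function(b1, se1, b2, se2) {
  if (any(se1 <= 0) || any(se2 <= 0)) abort("Standard errors must be > 0.")
  w1 <- 1 / se1^2
  w2 <- 1 / se2^2
  beta <- (w1 * b1 + w2 * b2) / (w1 + w2)
  se <- 1 / sqrt(w1 + w2)
  tibble(beta_fe = beta, se_fe = se, p_fe = two_sided_p(beta / se))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_i (b_i - pooled)^2)` with inverse-variance weights, compared
#' to a chi-square with `k - 1` degrees of freedom.
#'
#' @param betas,ses Numeric vectors of k >= 2 estimates and their standard
#'   errors.
#' @param pooled The pooled estimate the deviations are taken about
#'   (defaults to the fixed-effect inverse-variance mean).
#' @param df Degrees of freedom (defaults to `k - 1`; the Egger variant
#'   uses `k - 2`).
#' @return A list with `q`, `df`, `p`.
#' @export
cochran_q <- function(betas, ses, pooled = NULL, df = length(betas) - 1) {
  if (length(betas) < 2) abort("Cochran's Q needs at least two estimates.")
  w <- 1 / ses^2
  if (is.null(pooled)) pooled <- sum(w * betas) / sum(w)
  q <- sum(w * (betas - pooled)^2)
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE))
}

# profile log-likelihood of a random-effects normal model at tau2
re2_profile_ll <- function(tau2, b, v) {
  vv <- v + tau2
  mu <- sum(b / vv) / sum(1 / vv)
  -0.5 * sum(log(2 * pi * vv) + (b - mu)^2 / vv)
}

re2_one <- function(b, v) {
  ll0 <- -0.5 * sum(log(2 * pi * v) + b^2 / v)
  ub <- max(stats::var(b) * 4, diff(range(b))^2, max(v)) + 1e-12
  opt <- stats::optimize(re2_profile_ll, c(0, ub), b = b, v = v,
                         maximum = TRUE, tol = 1e-10)
  ll_zero <- re2_profile_ll(0, b, v)
  if (ll_zero >= opt$objective) {
    tau2 <- 0
    ll1 <- ll_zero
  } else {
    tau2 <- opt$maximum
    ll1 <- opt$objective
  }
  stat <- max(0, 2 * (ll1 - ll0))
  c(stat = stat, tau2 = tau2)
}

#' Han-Eskin random-effects (RE2) meta-analysis statistic
#'
#' Likelihood-ratio test of the joint null (mean effect 0, between-study
#' variance 0) against the alternative with a free mean and non-negative
#' between-study variance `tau2`. The statistic gains power under
#' heterogeneity because deviations between studies contribute through
#' `tau2`. P-values use the asymptotic equal-mixture tail
#' `0.5 chi2_1 + 0.5 chi2_2`, which is slightly conservative for two
#' studies.
#'
#' @param b1,se1,b2,se2 Numeric vectors of per-SNP study effects and
#'   standard errors.
#' @return A tibble with `stat_re2`, `p_re2`, `tau2`.
#' @export
re2_meta <- function(b1, se1, b2, se2) {
  if (any(se1 <= 0) || any(se2 <= 0)) abort("Standard errors must be > 0.")
  k <- length(b1)
  stat <- tau2 <- numeric(k)
  for (i in seq_len(k)) {
    r <- re2_one(c(b1[i], b2[i]), c(se1[i]^2, se2[i]^2))
    stat[i] <- r["stat"]
    tau2[i] <- r["tau2"]
  }
  p <- 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE) +
    0.5 * stats::pchisq(stat, 2, lower.tail = FALSE)
  tibble(stat_re2 = stat, p_re2 = p, tau2 = tau2)
}

#' Cross-disorder meta-analysis of a harmonized pair
#'
#' Combines the two traits' per-SNP effects with both the fixed-effect
#' model and the Han-Eskin RE2 model, attaches Cochran's Q (df = 1 for two
#' studies), and classifies SNPs as genome-wide significant
#' (`p < 5e-8`) or suggestive (`p < 1e-5`) under each model. Rows with
#' nominal heterogeneity (`p_q < 0.05`) are flagged, echoing the practice
#' of preferring RE2 in their presence.
#'
#' @param pair A `harmonized_pair`.
#' @param gw_p,suggestive_p Classification thresholds.
#' @return A tibble with one row per SNP: the fixed-effect and RE2
#'   statistics, heterogeneity Q and p, and `class_fe` / `class_re2`
#'   factors (`none`, `suggestive`, `genome-wide`).
#' @export
meta_analyse <- function(pair, gw_p = 5e-8, suggestive_p = 1e-5) {
  fe <- fixed_effect_meta(pair$beta_1, pair$se_1, pair$beta_2, pair$se_2)
  re2 <- re2_meta(pair$beta_1, pair$se_1, pair$beta_2, pair$se_2)
  w1 <- 1 / pair$se_1^2
  w2 <- 1 / pair$se_2^2
  q <- w1 * (pair$beta_1 - fe$beta_fe)^2 + w2 * (pair$beta_2 - fe$beta_fe)^2
  p_q <- stats::pchisq(q, 1, lower.tail = FALSE)
  classify <- function(p) {
    factor(ifelse(p < gw_p, "genome-wide",
                  ifelse(p < suggestive_p, "suggestive", "none")),
           levels = c("none", "suggestive", "genome-wide"))
  }
  out <- tibble(snp_id = pair$snp_id, chrom = pair$chrom, pos = pair$pos)
  out <- dplyr::bind_cols(out, fe, re2)
  out$q <- q
  out$p_q <- p_q
  out$heterogeneous <- p_q < 0.05
  out$class_fe <- classify(out$p_fe)
  out$class_re2 <- classify(out$p_re2)
  out
}

#' Group significant meta-analysis SNPs into loci
#'
#' Applies the genome-wide and suggestive thresholds on the chosen model's
#' p-value and groups significant SNPs into loci by LD-block membership
#' (SNPs absent from the reference form their own loci). The index SNP of
#' a locus is its smallest-p member.
#'
#' @param rows Output of [meta_analyse()].
#' @param ld An `ld_ref`.
#' @param model `"fe"` or `"re2"`.
#' @param gw_p,suggestive_p Thresholds (defaults 5e-8 and 1e-5).
#' @return A tibble with one row per locus: `locus`, `n_snps`,
#'   `index_snp`, `index_p`, `class`, and the member SNP IDs in a
#'   list-column `snps`. Empty when nothing passes `suggestive_p`.
#' @export
classify_loci <- function(rows, ld, model = c("re2", "fe"),
                          gw_p = 5e-8, suggestive_p = 1e-5) {
  model <- match.arg(model)
  pcol <- if (model == "fe") "p_fe" else "p_re2"
  sig <- rows[rows[[pcol]] < suggestive_p, ]
  if (nrow(sig) == 0L) {
    return(tibble(locus = integer(), n_snps = integer(),
                  index_snp = character(), index_p = numeric(),
                  class = character(), snps = list()))
  }
  hit <- match(sig$snp_id, ld$index$snp_id)
  bl <- ld$index$block[hit]
  bl[is.na(bl)] <- -seq_len(sum(is.na(bl)))  # singleton loci
  sig$.block <- bl
  sig$.p <- sig[[pcol]]
  sig %>%
    group_by(.data$.block) %>%
    summarise(
      n_snps = dplyr::n(),
      index_snp = snp_id[which.min(.data$.p)],
      index_p = min(.data$.p),
      class = if (min(.data$.p) < gw_p) "genome-wide" else "suggestive",
      snps = list(snp_id),
      .groups = "drop") %>%
    arrange(index_p) %>%
    mutate(locus = row_number()) %>%
    select(locus, n_snps, index_snp, index_p, class, snps)
}
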