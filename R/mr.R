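#' Attach Wald ratios and instrument strength to an instrument table
#'
#' Computes, per instrument, the Wald ratio `beta_outcome / beta_exposure`,
#' its first-order standard error `se_outcome / |beta_exposure|` (a
#' second-order delta-method version adding the exposure uncertainty is
#' available), and the approximate F-statistic
#' `(beta_exposure / se_exposure)^2`.
#'
#' @param x A tibble with columns `snp_id`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome` (and optionally p-values and alleles).
#' @param second_order Use the second-order ratio standard error
#'   `sqrt(sy^2 / bx^2 + by^2 sx^2 / bx^4)` (default `FALSE`).
#' @return The tibble with `wald_ratio`, `se_ratio`, `f_approx` columns,
#'   classed `mr_data`.
#' @export
mr_data <- function(x, second_order = FALSE) {
  need <- c("snp_id", "beta_exposure", "se_exposure", "beta_outcome",
            "se_outcome")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(sprintf("Missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  if (any(x$beta_exposure == 0)) {
    abort("Instruments with `beta_exposure` = 0 have undefined Wald ratios.")
  }
  if (any(x$se_exposure <= 0) || any(x$se_outcome <= 0)) {
    abort("Standard errors must be positive.")
  }
  x <- as_tibble(x)
  x$wald_ratio <- x$beta_outcome / x$beta_exposure
  x$se_ratio <- if (second_order) {
    sqrt(x$se_outcome^2 / x$beta_exposure^2 +
           x$beta_outcome^2 * x$se_exposure^2 / x$beta_exposure^4)
  } else {
    x$se_outcome / abs(x$beta_exposure)
  }
  x$f_approx <- (x$beta_exposure / x$se_exposure)^2
  structure(x, class = c("mr_data", class(as_tibble(x))))
}

#' Select and harmonize MR instruments from two summary-statistics tables
#'
#' Filters the exposure GWAS at the genome-wide significance threshold,
#' clumps the survivors at a stringent r-squared (default 0.001) so the
#' instruments are mutually independent, harmonizes them against the
#' outcome GWAS, and attaches Wald ratios and F-statistics. Instruments
#' absent from the outcome data are dropped and reported (no proxy search).
#'
#' @param exposure,outcome Validated summary-statistics tibbles.
#' @param ld An `ld_ref`.
#' @param p_thresh Exposure significance threshold (default 5e-8).
#' @param r2_max Clumping threshold (default 0.001).
#' @param drop_palindromic Passed to [harmonize_pair()].
#' @return An `mr_data` tibble, one row per instrument.
#' @export
select_instruments <- function(exposure, outcome, ld, p_thresh = 5e-8,
                               r2_max = 0.001, drop_palindromic = TRUE) {
  sig <- exposure[exposure$pvalue < p_thresh, ]
  n_sig <- nrow(sig)
  if (n_sig == 0L) {
    abort(sprintf("No exposure SNPs pass p < %g.", p_thresh))
  }
  absent <- setdiff(sig$snp_id, outcome$snp_id)
  if (length(absent) > 0) {
    inform(sprintf("%d significant exposure SNP(s) absent from the outcome data; dropped.",
                   length(absent)))
  }
  pair <- suppressMessages(
    harmonize_pair(sig, outcome, drop_palindromic = drop_palindromic))
  kept <- clump_snps(pair, ld, r2_max = r2_max, p_col = "p_1")
  tab <- pair[match(kept, pair$snp_id), ]
  if (nrow(tab) < 2) {
    h <- attr(pair, "harmonization")
    abort(sprintf(
      paste0("Fewer than 2 instruments survive: %d genome-wide significant, ",
             "%d lost to outcome lookup/harmonization, %d removed by clumping."),
      n_sig, n_sig - h$n_kept, h$n_kept - nrow(tab)))
  }
  out <- tibble(
    snp_id = tab$snp_id,
    effect_allele = tab$effect_allele, other_allele = tab$other_allele,
    beta_exposure = tab$beta_1, se_exposure = tab$se_1,
    p_exposure = tab$p_1,
    beta_outcome = tab$beta_2, se_outcome = tab$se_2,
    p_outcome = tab$p_2)
  mr_data(out)
}

new_mr_fit <- function(method, beta, se, p, n_snp, extra = list()) {
  structure(c(list(method = method, beta = unname(beta), se = unname(se),
                   p = unname(p),
                   ci_lower = unname(beta - 1.96 * se),
                   ci_upper = unname(beta + 1.96 * se),
                   or = exp(unname(beta)), n_snp = n_snp), extra),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("<mr_fit: %s> beta = %.4f (se %.4f), OR = %.3f (95%% CI %.3f-%.3f), p = %.3g, k = %d\n",
              x$method, x$beta, x$se, x$or, exp(x$ci_lower),
              exp(x$ci_upper), x$p, x$n_snp))
  if (!is.null(x$intercept)) {
    cat(sprintf("  Egger intercept = %.4f (se %.4f, p = %.3g)\n",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  invisible(x)
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted mean of the per-instrument Wald ratios with weights
#' `1 / se_ratio^2`. Under multiplicative random effects (the default) the
#' fixed-effect standard error is scaled by `max(1, sqrt(Q / (k - 1)))`,
#' inflating it when the instruments are over-dispersed; `mode = "fixed"`
#' gives the unscaled version. P-values are two-sided normal.
#'
#' @param data An `mr_data` tibble.
#' @param mode `"multiplicative_re"` (default) or `"fixed"`.
#' @return An `mr_fit`.
#' @export
mr_ivw <- function(data, mode = c("multiplicative_re", "fixed")) {
  mode <- match.arg(mode)
  r <- data$wald_ratio
  w <- 1 / data$se_ratio^2
  k <- length(r)
  beta <- sum(w * r) / sum(w)
  se <- 1 / sqrt(sum(w))
  if (mode == "multiplicative_re" && k > 1) {
    q <- sum(w * (r - beta)^2)
    se <- se * max(1, sqrt(q / (k - 1)))
  }
  new_mr_fit(paste0("ivw_", mode), beta, se, two_sided_p(beta / se), k)
}

#' MR-Egger regression
#'
#' Orients every instrument so the exposure effect is positive (flipping
#' outcome signs accordingly) and regresses the outcome effects on the
#' exposure effects with weights `1 / se_outcome^2` and a free intercept.
#' The slope is the pleiotropy-corrected causal estimate; the intercept
#' estimates the average directional pleiotropic effect. Standard errors
#' use the weighted regression with residual dispersion bounded below by 1
#' (multiplicative random effects); slope and intercept p-values are from
#' the t distribution with `k - 2` df.
#'
#' @param data An `mr_data` tibble with at least 2 (ideally >= 3)
#'   instruments.
#' @return An `mr_fit` with `intercept`, `intercept_se`, `intercept_p`
#'   components.
#' @export
mr_egger <- function(data) {
  k <- nrow(data)
  if (k < 2) abort("MR-Egger needs at least 2 instruments.")
  flip <- sign(data$beta_exposure)
  bx <- abs(data$beta_exposure)
  by <- data$beta_outcome * flip
  w <- 1 / data$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  disp <- max(sm$sigma, 1)
  co <- sm$coefficients
  beta <- co["bx", "Estimate"]
  se <- co["bx", "Std. Error"] / sm$sigma * disp
  int <- co["(Intercept)", "Estimate"]
  int_se <- co["(Intercept)", "Std. Error"] / sm$sigma * disp
  df <- k - 2
  pfun <- function(z) {
    if (df > 0) 2 * stats::pt(-abs(z), df) else NA_real_
  }
  new_mr_fit("egger", beta, se, pfun(beta / se), k,
             extra = list(intercept = unname(int),
                          intercept_se = unname(int_se),
                          intercept_p = pfun(int / int_se)))
}

weighted_median_estimate <- function(r, w) {
  ord <- order(r)
  r <- r[ord]
  w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(s)])
  i <- max(which(s < 0.5))
  r[i] + (r[i + 1] - r[i]) * (0.5 - s[i]) / (s[i + 1] - s[i])
}

#' Weighted-median MR estimate
#'
#' Interpolated weighted median of the Wald ratios with inverse-variance
#' weights: consistent when instruments carrying at least half the weight
#' are valid. The standard error comes from a seeded parametric bootstrap
#' that redraws each instrument's exposure and outcome effects from their
#' reported normal distributions.
#'
#' @param data An `mr_data` tibble with >= 3 instruments.
#' @param n_boot Bootstrap draws (default 5000).
#' @param seed Integer RNG seed for the bootstrap.
#' @return An `mr_fit`.
#' @export
mr_weighted_median <- function(data, n_boot = 5000, seed) {
  k <- nrow(data)
  if (k < 3) abort("The weighted median needs at least 3 instruments.")
  beta <- weighted_median_estimate(data$wald_ratio, 1 / data$se_ratio^2)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    bx <- rnorm(k, data$beta_exposure, data$se_exposure)
    by <- rnorm(k, data$beta_outcome, data$se_outcome)
    bx[bx == 0] <- .Machine$double.eps
    r <- by / bx
    s <- data$se_outcome / abs(bx)
    weighted_median_estimate(r, 1 / s^2)
  }, numeric(1))
  se <- stats::sd(boots)
  new_mr_fit("weighted_median", beta, se, two_sided_p(beta / se), k)
}

# weighted kernel-density mode of the ratio distribution
kde_mode <- function(r, w, phi) {
  s <- 0.9 * min(stats::sd(r), stats::mad(r)) * length(r)^(-1 / 5)
  if (!is.finite(s) || s <= 0) s <- stats::sd(r) * length(r)^(-1 / 5)
  if (!is.finite(s) || s <= 0) return(r[1])  # all ratios identical
  h <- phi * s
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 512)
  dens <- vapply(grid, function(g) {
    sum(w * stats::dnorm((g - r) / h))
  }, numeric(1))
  grid[which.max(dens)]
}

#' Mode-based MR estimators
#'
#' The causal estimate is the mode of the (weighted) kernel-smoothed
#' empirical density of the Wald ratios: consistent when the largest group
#' of instruments sharing a ratio is valid. Bandwidth follows the modified
#' Silverman rule `0.9 min(sd, mad) k^(-1/5)` scaled by `phi` (default 1);
#' standard errors come from a seeded parametric bootstrap.
#'
#' @param data An `mr_data` tibble with >= 3 instruments.
#' @param weighted Use inverse-variance weights (`TRUE`) or equal weights
#'   (`FALSE`, the simple mode).
#' @param phi Bandwidth scale factor (default 1).
#' @param n_boot Bootstrap draws (default 5000).
#' @param seed Integer RNG seed.
#' @return An `mr_fit`.
#' @export
mr_mode <- function(data, weighted = TRUE, phi = 1, n_boot = 5000, seed) {
  k <- nrow(data)
  if (k < 3) abort("Mode estimators need at least 3 instruments.")
  wts <- if (weighted) 1 / data$se_ratio^2 else rep(1, k)
  beta <- kde_mode(data$wald_ratio, wts / sum(wts), phi)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    bx <- rnorm(k, data$beta_exposure, data$se_exposure)
    by <- rnorm(k, data$beta_outcome, data$se_outcome)
    bx[bx == 0] <- .Machine$double.eps
    r <- by / bx
    s <- data$se_outcome / abs(bx)
    wb <- if (weighted) 1 / s^2 else rep(1, k)
    kde_mode(r, wb / sum(wb), phi)
  }, numeric(1))
  se <- stats::sd(boots)
  new_mr_fit(if (weighted) "weighted_mode" else "simple_mode",
             beta, se, two_sided_p(beta / se), k)
}

#' Heterogeneity statistics for MR fits
#'
#' Cochran's Q about the IVW estimate with Wald-ratio weights
#' (`df = k - 1`) and Q' about the MR-Egger fit (`df = k - 2`).
#'
#' @param data An `mr_data` tibble.
#' @return A tibble with one row per statistic: `method`, `q`, `df`, `p`.
#' @export
mr_heterogeneity <- function(data) {
  k <- nrow(data)
  ivw <- mr_ivw(data, mode = "fixed")
  qi <- cochran_q(data$wald_ratio, data$se_ratio, pooled = ivw$beta)
  eg <- mr_egger(data)
  flip <- sign(data$beta_exposure)
  resid_ratio <- (data$beta_outcome * flip -
                    (eg$intercept + eg$beta * abs(data$beta_exposure))) /
    abs(data$beta_exposure)
  w <- 1 / data$se_ratio^2
  qp <- sum(w * resid_ratio^2)
  tibble(method = c("ivw", "egger"),
         q = c(qi$q, qp),
         df = c(k - 1, k - 2),
         p = stats::pchisq(c(qi$q, qp), c(k - 1, k - 2),
                           lower.tail = FALSE))
}

#' Leave-one-out MR analysis
#'
#' Refits the chosen estimator k times, omitting one instrument each time;
#' a single influential (e.g. pleiotropic) instrument shows up as a
#' departure from the remaining refits.
#'
#' @param data An `mr_data` tibble.
#' @param method `"ivw"` (default), `"egger"` or `"weighted_median"`.
#' @param ... Passed to the estimator (e.g. `seed` for the weighted
#'   median).
#' @return A tibble with one row per omitted SNP (`omitted`, `beta`, `se`,
#'   `p`) plus a final row (`omitted = "none"`) for the full fit.
#' @export
mr_leave_one_out <- function(data, method = c("ivw", "egger",
                                              "weighted_median"), ...) {
  method <- match.arg(method)
  fitter <- switch(method,
                   ivw = function(d) mr_ivw(d),
                   egger = function(d) mr_egger(d),
                   weighted_median = function(d) mr_weighted_median(d, ...))
  rows <- lapply(seq_len(nrow(data)), function(i) {
    f <- fitter(data[-i, ])
    tibble(omitted = data$snp_id[i], beta = f$beta, se = f$se, p = f$p)
  })
  full <- fitter(data)
  bind_rows(c(rows, list(tibble(omitted = "none", beta = full$beta,
                                se = full$se, p = full$p))))
}

#' Run the full set of MR estimators
#'
#' @param data An `mr_data` tibble.
#' @param seed Integer RNG seed for the bootstrap-based estimators.
#' @param n_boot Bootstrap draws (default 5000).
#' @return A tibble with one row per method (IVW multiplicative RE,
#'   MR-Egger, weighted median, simple and weighted mode) plus the Egger
#'   intercept diagnostics as attributes `egger_intercept` and
#'   `heterogeneity`.
#' @export
mr_all <- function(data, seed, n_boot = 5000) {
  fits <- list(
    mr_ivw(data),
    mr_egger(data),
    mr_weighted_median(data, n_boot = n_boot, seed = seed),
    mr_mode(data, weighted = FALSE, n_boot = n_boot, seed = seed + 1),
    mr_mode(data, weighted = TRUE, n_boot = n_boot, seed = seed + 2))
  out <- bind_rows(lapply(fits, tidy.mr_fit))
  attr(out, "egger_intercept") <- fits[[2]][c("intercept", "intercept_se",
                                              "intercept_p")]
  attr(out, "heterogeneity") <- mr_heterogeneity(data)
  out
}
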