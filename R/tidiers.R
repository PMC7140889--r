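#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an MR fit into a one-row tibble
#'
#' @param x An `mr_fit`.
#' @param ... Unused.
#' @return A tibble with `method`, `n_snp`, `estimate`, `std.error`,
#'   `p.value`, `conf.low`, `conf.high`, `or`.
#' @method tidy mr_fit
#' @export
tidy.mr_fit <- function(x, ...) {
  tibble(method = x$method, n_snp = x$n_snp, estimate = x$beta,
         std.error = x$se, p.value = x$p,
         conf.low = x$ci_lower, conf.high = x$ci_upper, or = x$or)
}

#' @rdname tidy.mr_fit
#' @method glance mr_fit
#' @export
glance.mr_fit <- function(x, ...) {
  out <- tidy(x)
  if (!is.null(x$intercept)) {
    out$intercept <- x$intercept
    out$intercept_p <- x$intercept_p
  }
  out
}

#' Tidy an LD score regression fit
#'
#' One row per estimated quantity (heritability, intercept, genetic
#' correlation, genetic covariance), with standard errors where estimated.
#'
#' @param x An `ldsc_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`.
#' @method tidy ldsc_fit
#' @export
tidy.ldsc_fit <- function(x, ...) {
  if (x$type == "h2") {
    out <- tibble(
      term = c("h2_observed", "intercept"),
      estimate = c(x$h2_obs, x$intercept),
      std.error = c(x$h2_se, x$intercept_se))
    if (!is.null(x$h2_liab)) {
      out <- bind_rows(out, tibble(term = "h2_liability",
                                   estimate = x$h2_liab,
                                   std.error = x$h2_liab_se))
    }
    out
  } else {
    tibble(
      term = c("rg", "gencov", "gencov_intercept", "h2_obs_trait1",
               "h2_obs_trait2"),
      estimate = c(x$rg, x$gencov, x$gencov_intercept, x$h2_1, x$h2_2),
      std.error = c(x$rg_se, NA, x$gencov_intercept_se, NA, NA))
  }
}

#' @rdname tidy.ldsc_fit
#' @method glance ldsc_fit
#' @export
glance.ldsc_fit <- function(x, ...) {
  base <- tibble(n_snps_used = x$n_snps_used, m = x$m,
                 jackknife_blocks = x$jackknife_blocks)
  if (x$type == "h2") {
    base$h2_obs <- x$h2_obs
    base$intercept <- x$intercept
    if (!is.null(x$h2_liab)) base$h2_liab <- x$h2_liab
  } else {
    base$rg <- x$rg
    base$rg_p <- x$rg_p
  }
  base
}

#' Tidy a SECA result into its cell table
#'
#' @param x A `seca_result`.
#' @param ... Unused.
#' @return The 144-cell grid tibble (with Fisher columns).
#' @method tidy seca_result
#' @export
tidy.seca_result <- function(x, ...) {
  as_tibble(x$cells)
}

#' @rdname tidy.seca_result
#' @method glance seca_result
#' @export
glance.seca_result <- function(x, ...) {
  tibble(n_independent = x$n_independent,
         n_sig_subsets = x$binomial$n_sig_subsets,
         p_binomial = x$binomial$p_binomial,
         p_fsig_permuted = x$permutation$p_fsig_permuted,
         p_fsig_ci_lower = x$permutation$ci[["lower"]],
         p_fsig_ci_upper = x$permutation$ci[["upper"]],
         p_ftmin_permuted = x$permutation$p_ftmin_permuted,
         min_p_ft = x$permutation$min_p_ft)
}
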