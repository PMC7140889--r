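published_instruments <- function() {
  mr_data(readr::read_tsv(
    fixture_path("endometriosis_migraine_mr_instruments.tsv"),
    show_col_types = FALSE)[, c("snp_id", "effect_allele", "other_allele",
                                "beta_exposure", "se_exposure",
                                "p_exposure", "beta_outcome", "se_outcome",
                                "p_outcome")])
}

# an mr_data tibble whose ratio/se columns are exactly the printed ones
printed_ratio_data <- function() {
  tab <- readr::read_tsv(
    fixture_path("endometriosis_migraine_mr_instruments.tsv"),
    show_col_types = FALSE)
  mr_data(tibble::tibble(
    snp_id = tab$snp_id,
    beta_exposure = 1, se_exposure = 0.1,
    beta_outcome = tab$wald_ratio, se_outcome = tab$se_ratio))
}

test_that("Wald ratios and F-statistics follow their definitions", {
  iv <- published_instruments()
  rs <- iv[iv$snp_id == "rs74485684", ]
  expect_equal(round(rs$wald_ratio, 2), 0.36)
  expect_equal(rs$se_ratio, 0.01 / 0.11)
  expect_equal(mr_data(tibble::tibble(
    snp_id = "a", beta_exposure = 0.2, se_exposure = 0.05,
    beta_outcome = 0, se_outcome = 0.01))$wald_ratio, 0)
  expect_error(mr_data(tibble::tibble(
    snp_id = "a", beta_exposure = 0, se_exposure = 0.05,
    beta_outcome = 0.1, se_outcome = 0.01)), "undefined")
  expect_equal(mr_data(tibble::tibble(
    snp_id = "a", beta_exposure = 0.05, se_exposure = 0.05,
    beta_outcome = 0, se_outcome = 0.01))$f_approx, 1)
  expect_equal(mr_data(tibble::tibble(
    snp_id = "a", beta_exposure = 2, se_exposure = 1,
    beta_outcome = 0, se_outcome = 0.01))$f_approx, 4)
  # F equals the squared z implied by the (unrounded) exposure p-value
  iv2 <- gen_mr_scenario(5, 0.2, seed = 3)
  z <- stats::qnorm(iv2$p_exposure / 2, lower.tail = FALSE)
  expect_equal(iv2$f_approx, z^2, tolerance = 1e-8)
})

test_that("the second-order ratio se matches Monte-Carlo propagation", {
  bx <- 0.15
  sx <- 0.02
  by <- 0.05
  sy <- 0.01
  d2 <- mr_data(tibble::tibble(snp_id = "a", beta_exposure = bx,
                               se_exposure = sx, beta_outcome = by,
                               se_outcome = sy), second_order = TRUE)
  set.seed(5)
  sims <- rnorm(2e5, by, sy) / rnorm(2e5, bx, sx)
  expect_equal(d2$se_ratio, sd(sims), tolerance = 0.05)
})

test_that("IVW reduces to means and single ratios in degenerate cases", {
  d <- mr_data(tibble::tibble(
    snp_id = c("a", "b", "c"), beta_exposure = c(0.1, 0.2, 0.4),
    se_exposure = 0.01,
    beta_outcome = c(0.05, 0.02, -0.04), se_outcome = c(0.01, 0.02, 0.04)))
  # equal ratio ses: plain mean of ratios
  expect_equal(mr_ivw(d, mode = "fixed")$beta, mean(d$wald_ratio))
  single <- mr_ivw(d[1, ], mode = "fixed")
  expect_equal(single$beta, d$wald_ratio[1])
  # IVW lies within the ratio range for positive weights
  iv <- gen_mr_scenario(15, 0.2, pleiotropy_sd = 0.02, seed = 7)
  fit <- mr_ivw(iv)
  expect_gte(fit$beta, min(iv$wald_ratio))
  expect_lte(fit$beta, max(iv$wald_ratio))
})

test_that("multiplicative random effects reproduce the published IVW summary", {
  fit <- mr_ivw(printed_ratio_data())
  expect_equal(round(fit$or, 2), 0.98)
  expect_equal(round(fit$se, 2), 0.05)
  fit_fixed <- mr_ivw(printed_ratio_data(), mode = "fixed")
  expect_equal(round(fit_fixed$se, 2), 0.03)
})

test_that("Egger recovers exact lines and agrees with a weighted lm oracle", {
  d <- mr_data(tibble::tibble(
    snp_id = letters[1:4], beta_exposure = c(0.1, 0.2, -0.3, 0.4),
    se_exposure = 0.01, beta_outcome = c(0.05, 0.1, -0.15, 0.2),
    se_outcome = 0.01))
  fit <- mr_egger(d)
  expect_equal(fit$beta, 0.5, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)

  # two instruments interpolate exactly with zero residual heterogeneity
  d2 <- mr_data(tibble::tibble(
    snp_id = c("a", "b"), beta_exposure = c(0.1, 0.3), se_exposure = 0.01,
    beta_outcome = c(0.07, 0.12), se_outcome = 0.01))
  het2 <- mr_heterogeneity(d2)
  expect_equal(het2$q[het2$method == "egger"], 0, tolerance = 1e-10)

  # reference implementation check on noisy data
  iv <- gen_mr_scenario(12, 0.2, pleiotropy_mean = 0.02,
                        pleiotropy_sd = 0.01, seed = 11)
  fit2 <- mr_egger(iv)
  ref <- stats::lm(I(iv$beta_outcome * sign(iv$beta_exposure)) ~
                     abs(iv$beta_exposure), weights = 1 / iv$se_outcome^2)
  expect_equal(fit2$beta, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(fit2$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
  expect_error(mr_egger(iv[1, ]), "at least 2")
})

test_that("the weighted median interpolates and reproduces the published value", {
  d <- mr_data(tibble::tibble(
    snp_id = letters[1:5], beta_exposure = 1, se_exposure = 0.1,
    beta_outcome = c(0.1, 0.3, 0.2, 0.5, 0.4), se_outcome = 1))
  # equal weights, odd k: exactly the middle ratio
  expect_equal(mr_weighted_median(d, n_boot = 50, seed = 1)$beta, 0.3)

  fit <- mr_weighted_median(printed_ratio_data(), n_boot = 2000, seed = 2)
  expect_equal(round(fit$beta, 2), -0.09)
  # the estimate lies within the ratio range
  expect_gte(fit$beta, min(printed_ratio_data()$wald_ratio))
  expect_lte(fit$beta, max(printed_ratio_data()$wald_ratio))
})

test_that("bootstrap standard errors are stable as draws double", {
  d <- printed_ratio_data()
  se1 <- mr_weighted_median(d, n_boot = 5000, seed = 31)$se
  se2 <- mr_weighted_median(d, n_boot = 10000, seed = 32)$se
  expect_lt(abs(se2 - se1) / se1, 0.05)
})

test_that("mode estimators find the dominant cluster", {
  d <- mr_data(tibble::tibble(
    snp_id = letters[1:6], beta_exposure = 1, se_exposure = 0.1,
    beta_outcome = c(0.2, 0.2, 0.2, 0.2, 0.8, 0.85), se_outcome = 0.05))
  fit <- mr_mode(d, weighted = FALSE, n_boot = 100, seed = 4)
  expect_lt(abs(fit$beta - 0.2), 0.1)
  all_same <- mr_data(tibble::tibble(
    snp_id = letters[1:4], beta_exposure = 1, se_exposure = 0.1,
    beta_outcome = 0.3, se_outcome = 0.05))
  expect_equal(mr_mode(all_same, n_boot = 50, seed = 5)$beta, 0.3,
               tolerance = 1e-8)
})

test_that("heterogeneity degrees of freedom follow the instrument count", {
  iv <- published_instruments()
  het <- mr_heterogeneity(iv)
  expect_equal(het$df[het$method == "ivw"], 10)
  expect_equal(het$df[het$method == "egger"], 9)
  # homogeneous instruments: Q near its df on average
  qs <- vapply(1:30, function(s) {
    d <- gen_mr_scenario(11, 0.2, seed = 200 + s)
    mr_heterogeneity(d)$q[1]
  }, numeric(1))
  expect_lt(abs(mean(qs) - 10), 3 * sqrt(2 * 10 / 30))
})

test_that("leave-one-out refits collapse for identical instruments", {
  d <- mr_data(tibble::tibble(
    snp_id = letters[1:5], beta_exposure = 0.2, se_exposure = 0.02,
    beta_outcome = 0.06, se_outcome = 0.01))
  loo <- mr_leave_one_out(d)
  expect_equal(nrow(loo), 6)
  expect_true(all(abs(loo$beta - loo$beta[6]) < 1e-12))
})

test_that("estimators are equivariant under exposure rescaling", {
  iv <- gen_mr_scenario(11, 0.25, pleiotropy_sd = 0.01, seed = 9)
  c0 <- 2.5
  scaled <- mr_data(tibble::tibble(
    snp_id = iv$snp_id,
    beta_exposure = iv$beta_exposure * c0,
    se_exposure = iv$se_exposure * c0,
    beta_outcome = iv$beta_outcome, se_outcome = iv$se_outcome))
  expect_equal(mr_ivw(scaled)$beta, mr_ivw(iv)$beta / c0,
               tolerance = 1e-10)
  expect_equal(mr_egger(scaled)$beta, mr_egger(iv)$beta / c0,
               tolerance = 1e-10)
  expect_equal(mr_weighted_median(scaled, n_boot = 10, seed = 1)$beta,
               mr_weighted_median(iv, n_boot = 10, seed = 1)$beta / c0,
               tolerance = 1e-10)
})

test_that("fixed-effect IVW equals Egger with the intercept constrained out", {
  iv <- gen_mr_scenario(8, 0.2, seed = 13)
  # no-intercept weighted regression of oriented effects = IVW
  flip <- sign(iv$beta_exposure)
  ref <- stats::lm(I(iv$beta_outcome * flip) ~ 0 + abs(iv$beta_exposure),
                   weights = 1 / iv$se_outcome^2)
  expect_equal(mr_ivw(iv, mode = "fixed")$beta, unname(coef(ref)[1]),
               tolerance = 1e-10)
})

test_that("instrument selection mirrors the threshold-clump-harmonize flow", {
  # 338 significant SNPs in 11 tight blocks -> 11 instruments
  m <- 600
  block_size <- 50
  ld <- gen_ld_reference(m, block_size, rho = 0.95)
  exposure <- make_sumstats(m, seed = 17)
  exposure$snp_id <- ld_snps(ld)
  exposure$pvalue <- runif(m, 0.1, 1)
  set.seed(18)
  sig <- unlist(lapply(0:10, function(b) {
    b * block_size + sample.int(block_size, c(rep(31, 8), 30, 30, 30)[b + 1])
  }))
  stopifnot(length(sig) == 338)
  exposure$pvalue[sig] <- runif(338, 1e-20, 4e-8)
  outcome <- make_sumstats(m, seed = 19)
  outcome$snp_id <- ld_snps(ld)
  iv <- suppressMessages(
    select_instruments(exposure, outcome, ld, p_thresh = 5e-8,
                       r2_max = 0.001))
  expect_equal(nrow(iv), 11)
  expect_true(all(iv$p_exposure < 5e-8))

  # p_thresh = 1: clumping alone decides the count
  iv_all <- suppressMessages(
    select_instruments(exposure, outcome, ld, p_thresh = 1,
                       r2_max = 0.001))
  expect_equal(nrow(iv_all), 12)

  # all significant SNPs in one block: a single instrument is an error
  exposure2 <- exposure
  exposure2$pvalue <- runif(m, 0.1, 1)
  exposure2$pvalue[1:20] <- 1e-10
  expect_error(
    suppressMessages(select_instruments(exposure2, outcome, ld)),
    "Fewer than 2")
})

test_that("IVW p-values are calibrated under the causal null", {
  ps <- vapply(1:200, function(s) {
    d <- gen_mr_scenario(11, 0, seed = 3000 + s)
    mr_ivw(d)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.06)
})
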