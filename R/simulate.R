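#' Configuration for the paired-GWAS generator
#'
#' Bundles the parameters of the bivariate polygenic model under which
#' synthetic summary statistics are generated. The defaults are the
#' desk-scale study conditions used throughout the package's validation:
#' 20,000 SNPs, 50,000 samples per trait, SNP heritability 0.10 for both
#' traits and genetic correlation 0.38, with AR(1) LD blocks of 50 SNPs at
#' rho = 0.5.
#'
#' @param m_snps Number of SNPs.
#' @param n1,n2 Effective sample sizes of the two traits.
#' @param h2_1,h2_2 True SNP heritabilities in `[0, 1]`.
#' @param rg True genetic correlation in `[-1, 1]`.
#' @param block_size SNPs per LD block.
#' @param rho AR(1) LD parameter in `[0, 1)`.
#' @param causal_fraction Fraction of SNPs carrying nonzero true effects
#'   (default 1: the infinitesimal model).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(m_snps = 20000, n1 = 50000, n2 = 50000,
                         h2_1 = 0.10, h2_2 = 0.10, rg = 0.38,
                         block_size = 50, rho = 0.5,
                         causal_fraction = 1) {
  check_number(m_snps, "m_snps", lower = 2)
  check_number(n1, "n1", lower = 1)
  check_number(n2, "n2", lower = 1)
  check_number(h2_1, "h2_1", lower = 0, upper = 1)
  check_number(h2_2, "h2_2", lower = 0, upper = 1)
  check_number(rg, "rg", lower = -1, upper = 1)
  check_number(block_size, "block_size", lower = 1)
  check_number(rho, "rho", lower = 0, upper = 1, closed_upper = FALSE)
  check_number(causal_fraction, "causal_fraction", lower = 0, upper = 1,
               closed_lower = FALSE)
  structure(list(m_snps = as.integer(m_snps), n1 = n1, n2 = n2,
                 h2_1 = h2_1, h2_2 = h2_2, rg = rg,
                 block_size = as.integer(block_size), rho = rho,
                 causal_fraction = causal_fraction),
            class = "synth_config")
}

#' Generate an AR(1) block-diagonal LD reference
#'
#' Builds `ceiling(m_snps / block_size)` blocks whose correlation matrices
#' follow `r[i, j] = rho^|i - j|`; such matrices are positive definite for
#' `rho` in `[0, 1)`. SNP IDs are `rs0000001`, `rs0000002`, ... with
#' positions every 1 kb on chromosome 1 (matching [gen_joint_sumstats()]).
#'
#' @param m_snps Total number of SNPs.
#' @param block_size SNPs per block (last block may be smaller).
#' @param rho AR(1) parameter in `[0, 1)`.
#' @return An `ld_ref` object.
#' @export
gen_ld_reference <- function(m_snps, block_size = 50, rho = 0.5) {
  check_number(m_snps, "m_snps", lower = 1)
  check_number(block_size, "block_size", lower = 1)
  check_number(rho, "rho", lower = 0, upper = 1, closed_upper = FALSE)
  ids <- sprintf("rs%07d", seq_len(m_snps))
  starts <- seq(1, m_snps, by = block_size)
  blocks <- lapply(starts, function(s) {
    e <- min(s + block_size - 1, m_snps)
    k <- e - s + 1
    list(snps = ids[s:e], r = rho^abs(outer(seq_len(k), seq_len(k), "-")))
  })
  ld_reference(blocks, validate = FALSE)
}

# positions and ids consistent across generators
synth_snp_map <- function(m_snps) {
  tibble(snp_id = sprintf("rs%07d", seq_len(m_snps)),
         chrom = "1", pos = seq_len(m_snps) * 1000L)
}

#' Generate paired GWAS summary statistics with known truth
#'
#' Simulates two overlapping summary-statistics tables under the bivariate
#' polygenic model assumed by LD score regression. Per SNP j, true effects
#' `(beta_1j, beta_2j)` are drawn jointly with variances `h2_k / m_causal`
#' and correlation `rg`; observed z-scores per block are
#' `z_k = sqrt(n_k) R beta_k + eps` with `eps ~ MVN(0, R)`, independently
#' across traits (no sample overlap). Reported effects are on the z scale:
#' `beta = z / sqrt(n)`, `se = 1 / sqrt(n)`, two-sided normal p-values.
#'
#' @param cfg A [synth_config()].
#' @param ld An `ld_ref` covering exactly `cfg$m_snps` SNPs, typically from
#'   [gen_ld_reference()].
#' @param seed Integer RNG seed; generation is bit-reproducible given it.
#' @param palindromic_fraction Fraction of SNPs assigned palindromic (A/T or
#'   C/G) allele pairs, to exercise harmonization (default 0.15).
#' @return A list with elements `stats1`, `stats2` (summary-statistics
#'   tibbles) and `truth` (per-SNP true effects and the parameter vector).
#' @export
gen_joint_sumstats <- function(cfg, ld, seed, palindromic_fraction = 0.15) {
  stopifnot(inherits(cfg, "synth_config"), inherits(ld, "ld_ref"))
  m <- cfg$m_snps
  if (nrow(ld$index) != m) {
    abort("LD reference SNP count must equal `cfg$m_snps`.")
  }
  set.seed(seed)
  causal <- if (cfg$causal_fraction < 1) {
    sort(sample.int(m, max(1, round(m * cfg$causal_fraction))))
  } else seq_len(m)
  mc <- length(causal)
  # joint true effects: per-SNP covariance [h2_1, rg*sqrt(h2_1*h2_2);
  #                                         ., h2_2] / m_causal
  s1 <- sqrt(cfg$h2_1 / mc)
  s2 <- sqrt(cfg$h2_2 / mc)
  e1 <- rnorm(mc)
  e2 <- cfg$rg * e1 + sqrt(1 - cfg$rg^2) * rnorm(mc)
  beta1 <- beta2 <- numeric(m)
  beta1[causal] <- s1 * e1
  beta2[causal] <- s2 * e2

  z1 <- numeric(m)
  z2 <- numeric(m)
  chol_cache <- list()
  offset <- 0L
  for (bl in ld$blocks) {
    k <- length(bl$snps)
    rows <- offset + seq_len(k)
    key <- as.character(k)
    if (is.null(chol_cache[[key]])) {
      chol_cache[[key]] <- chol(bl$r)  # all equal-size blocks share R
    }
    U <- chol_cache[[key]]
    z1[rows] <- sqrt(cfg$n1) * drop(bl$r %*% beta1[rows]) +
      drop(crossprod(U, rnorm(k)))
    z2[rows] <- sqrt(cfg$n2) * drop(bl$r %*% beta2[rows]) +
      drop(crossprod(U, rnorm(k)))
    offset <- offset + k
  }

  map <- synth_snp_map(m)
  map$snp_id <- ld$index$snp_id  # honour the reference's IDs
  pairs_np <- c("AG", "GA", "AC", "CA", "TC", "CT", "TG", "GT")
  pairs_p <- c("AT", "TA", "CG", "GC")
  pal <- runif(m) < palindromic_fraction
  pick <- character(m)
  pick[pal] <- sample(pairs_p, sum(pal), replace = TRUE)
  pick[!pal] <- sample(pairs_np, sum(!pal), replace = TRUE)
  ea <- substr(pick, 1, 1)
  oa <- substr(pick, 2, 2)
  eaf <- runif(m, 0.05, 0.95)

  mk <- function(z, n_k) {
    tibble(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
           effect_allele = ea, other_allele = oa,
           beta = z / sqrt(n_k), se = 1 / sqrt(n_k),
           pvalue = two_sided_p(z), n = n_k, eaf = eaf)
  }
  list(stats1 = mk(z1, cfg$n1), stats2 = mk(z2, cfg$n2),
       truth = list(beta1 = beta1, beta2 = beta2, causal = causal,
                    params = c(h2_1 = cfg$h2_1, h2_2 = cfg$h2_2,
                               rg = cfg$rg)))
}

#' Generate a two-sample MR scenario with known causal effect
#'
#' Simulates independent instruments: exposure effects are drawn at
#' genome-wide-significant magnitude with the effect allele coded
#' exposure-increasing, and the outcome effect of each instrument is
#' `theta * beta_exposure + alpha + noise` with the pleiotropic intercept
#' `alpha ~ Normal(pleiotropy_mean, pleiotropy_sd^2)`. A nonzero
#' `pleiotropy_mean` injects directional pleiotropy (biasing IVW but not the
#' Egger slope); a nonzero `pleiotropy_sd` injects balanced pleiotropy
#' (heterogeneity).
#'
#' @param n_iv Number of instruments (>= 2; MR-Egger is undefined below 2).
#' @param theta True causal effect of exposure on outcome.
#' @param pleiotropy_mean,pleiotropy_sd Mean and sd of the per-instrument
#'   pleiotropic effect (defaults 0).
#' @param seed Integer RNG seed.
#' @return A tibble of class `mr_data` (see [mr_data()]) with attribute
#'   `truth` recording `theta` and the drawn pleiotropic effects.
#' @export
gen_mr_scenario <- function(n_iv, theta, pleiotropy_mean = 0,
                            pleiotropy_sd = 0, seed) {
  if (n_iv < 2) {
    abort("`n_iv` must be at least 2 (MR-Egger is undefined otherwise).")
  }
  set.seed(seed)
  bx <- runif(n_iv, 0.08, 0.18)
  se_x <- bx / runif(n_iv, 6.5, 12)     # exposure |z| > 6.5 => p < 5e-8
  alpha <- rnorm(n_iv, pleiotropy_mean, pleiotropy_sd)
  se_y <- runif(n_iv, 0.008, 0.014)
  by <- theta * bx + alpha + rnorm(n_iv, 0, se_y)
  tab <- tibble(
    snp_id = sprintf("iv%03d", seq_len(n_iv)),
    effect_allele = "A", other_allele = "G",
    beta_exposure = bx, se_exposure = se_x,
    p_exposure = two_sided_p(bx / se_x),
    beta_outcome = by, se_outcome = se_y,
    p_outcome = two_sided_p(by / se_y))
  out <- mr_data(tab)
  attr(out, "truth") <- list(theta = theta, alpha = alpha)
  out
}

#' Generate a gene annotation partitioning the synthetic SNPs
#'
#' Splits the `m_snps` synthetic SNP positions into `n_genes` contiguous,
#' non-overlapping genes (the "+/- 0 kb" gene-boundary convention: a SNP
#' belongs to a gene iff its position lies within the gene's start-stop
#' interval, 1-based inclusive).
#'
#' @param m_snps Number of SNPs (positioned as in [gen_joint_sumstats()]).
#' @param n_genes Number of genes (<= `m_snps`).
#' @param seed Integer RNG seed (gene sizes are drawn randomly).
#' @return A tibble with columns `chrom`, `start`, `stop`, `gene`.
#' @export
gen_gene_annotation <- function(m_snps, n_genes, seed) {
  if (n_genes > m_snps) {
    abort("`n_genes` must not exceed `m_snps`.")
  }
  set.seed(seed)
  map <- synth_snp_map(m_snps)
  cuts <- sort(sample(seq_len(m_snps - 1), n_genes - 1))
  firsts <- c(1L, cuts + 1L)
  lasts <- c(cuts, m_snps)
  tibble(chrom = "1",
         start = map$pos[firsts],
         stop = map$pos[lasts],
         gene = sprintf("GENE%04d", seq_len(n_genes)))
}

#' Generate random gene sets over a gene universe
#'
#' @param gene_symbols Character vector of gene symbols (the universe).
#' @param n_terms Number of terms to draw.
#' @param size_range Two-element integer range of term sizes; must lie
#'   within `[1, length(gene_symbols)]`.
#' @param seed Integer RNG seed.
#' @return A gene-set tibble with columns `term_id`, `term_name`, `genes`
#'   (list-column), as returned by [read_gmt()].
#' @export
gen_gene_sets <- function(gene_symbols, n_terms, size_range = c(5, 50),
                          seed) {
  if (size_range[1] < 1 || size_range[2] > length(gene_symbols) ||
      size_range[1] > size_range[2]) {
    abort("`size_range` must lie within [1, number of genes].")
  }
  set.seed(seed)
  sizes <- sample(seq(size_range[1], size_range[2]), n_terms, replace = TRUE)
  tibble(
    term_id = sprintf("TERM:%04d", seq_len(n_terms)),
    term_name = sprintf("synthetic term %d", seq_len(n_terms)),
    genes = lapply(sizes, function(s) sample(gene_symbols, s)))
}
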