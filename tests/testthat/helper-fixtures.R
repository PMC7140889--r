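# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files written by the tests themselves.

make_sumstats <- function(n = 5, seed = 1, chrom = "1", prefix = "rs") {
  set.seed(seed)
  tibble::tibble(
    snp_id = sprintf("%s%04d", prefix, seq_len(n)),
    chrom = chrom,
    pos = seq_len(n) * 1000L,
    effect_allele = "A",
    other_allele = "G",
    beta = stats::rnorm(n, 0, 0.1),
    se = stats::runif(n, 0.01, 0.05),
    pvalue = stats::runif(n),
    n = 10000,
    eaf = stats::runif(n, 0.1, 0.9))
}

write_sumstats_fixture <- function(x, path) {
  out <- x
  names(out) <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P", "N",
                  "FRQ")[seq_along(out)]
  readr::write_tsv(out, path)
  path
}

# a harmonized-pair-shaped tibble built directly (bypassing harmonize_pair)
make_pair <- function(n, seed = 1, rho_sign = 0) {
  set.seed(seed)
  s1 <- sign(stats::rnorm(n))
  s2 <- ifelse(stats::runif(n) < (1 + rho_sign) / 2, s1, -s1)
  tibble::tibble(
    snp_id = sprintf("rs%05d", seq_len(n)),
    chrom = "1", pos = seq_len(n) * 1000L,
    effect_allele = "A", other_allele = "G",
    beta_1 = s1 * abs(stats::rnorm(n, 0, 0.1)),
    se_1 = 0.02, p_1 = stats::runif(n), n_1 = 10000,
    beta_2 = s2 * abs(stats::rnorm(n, 0, 0.1)),
    se_2 = 0.02, p_2 = stats::runif(n), n_2 = 10000)
}

# AR(1) correlation matrix
ar1_mat <- function(k, rho) rho^abs(outer(seq_len(k), seq_len(k), "-"))

fixture_path <- function(name) {
  system.file("extdata", name, package = "crosstrait", mustWork = TRUE)
}
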