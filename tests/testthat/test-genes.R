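test_that("SNP-to-gene assignment matches a double-loop interval oracle", {
  set.seed(3)
  ann <- tibble::tibble(
    chrom = c("1", "1", "2"),
    start = c(100, 500, 200),
    stop = c(300, 900, 400),
    gene = c("G1", "G2", "G3"))
  stats <- tibble::tibble(
    snp_id = sprintf("s%02d", 1:40), chrom = sample(c("1", "2"), 40, TRUE),
    pos = sample(1000, 40), pvalue = runif(40))
  got <- suppressMessages(assign_snps_to_genes(stats, ann))
  oracle <- list()
  for (i in seq_len(nrow(ann))) {
    for (j in seq_len(nrow(stats))) {
      if (stats$chrom[j] == ann$chrom[i] &&
          stats$pos[j] >= ann$start[i] && stats$pos[j] <= ann$stop[i]) {
        oracle[[length(oracle) + 1]] <- paste(ann$gene[i], stats$snp_id[j])
      }
    }
  }
  expect_setequal(paste(got$gene, got$snp_id), unlist(oracle))

  # boundary inclusion: a SNP at pos = start belongs to the gene
  b <- suppressMessages(assign_snps_to_genes(
    tibble::tibble(snp_id = "x", chrom = "1", pos = 100, pvalue = 0.5),
    ann))
  expect_equal(b$gene, "G1")

  # malformed rows are dropped with a warning
  ann_bad <- ann
  ann_bad$start[2] <- 2000
  expect_warning(suppressMessages(assign_snps_to_genes(stats, ann_bad)),
                 "malformed")
})

test_that("best-SNP test matches its closed forms", {
  # single SNP: the gene p is the SNP p up to Monte Carlo error
  p1 <- best_snp_test(0.3, matrix(1, 1, 1), n_sim_max = 2e4, seed = 1)
  expect_lt(abs(p1 - 0.3), 3 * sqrt(0.3 * 0.7 / 2e4))

  # perfect LD: the minimum of m identical tests is one test
  m <- 5
  r <- matrix(1, m, m)
  pp <- best_snp_test(rep(0.2, m), r, n_sim_max = 2e4, seed = 2)
  expect_lt(abs(pp - 0.2), 3 * sqrt(0.2 * 0.8 / 2e4))

  # the Monte Carlo floor and monotonicity in the observed minimum
  tiny <- best_snp_test(1e-12, matrix(1, 1, 1), n_sim_max = 1e4, seed = 3)
  expect_gte(tiny, 1 / (1e4 + 1))
  pa <- best_snp_test(c(0.05, 0.5, 0.7), diag(3), n_sim_max = 1e4, seed = 4)
  pb <- best_snp_test(c(0.10, 0.5, 0.7), diag(3), n_sim_max = 1e4, seed = 4)
  expect_lte(pa, pb)
})

test_that("identity-LD gene p-values follow the Sidak closed form", {
  m <- 8
  q <- 0.02
  n_sim <- 5e4
  got <- best_snp_test(c(q, runif(m - 1, 0.5, 1)), diag(m),
                       n_sim_max = n_sim, n_sim_min = n_sim, seed = 5)
  sidak <- 1 - (1 - q)^m
  expect_lt(abs(got - sidak), 3 * sqrt(sidak * (1 - sidak) / n_sim))
})

test_that("effective gene counts follow the Li-Ji eigenvalue rule", {
  # independent top SNPs: every gene counts fully
  gt <- tibble::tibble(top_snp = sprintf("s%d", 1:7))
  ld <- ld_independent(gt$top_snp)
  expect_equal(effective_genes(gt, ld), 7)

  # two genes tagged by perfectly correlated SNPs contribute 1
  r <- matrix(c(1, 1, 1, 1), 2)
  ld2 <- ld_reference(list(list(snps = c("a", "b"), r = r)),
                      validate = FALSE)
  expect_equal(effective_genes(tibble::tibble(top_snp = c("a", "b")), ld2),
               1)

  # AR(1) block against an independently coded eigenvalue oracle
  k <- 5
  rho <- 0.6
  r5 <- ar1_mat(k, rho)
  ids <- sprintf("t%d", 1:k)
  dimnames(r5) <- list(ids, ids)
  ld5 <- ld_reference(list(list(snps = ids, r = r5)))
  got <- effective_genes(tibble::tibble(top_snp = ids), ld5,
                         r2_thresh = 0.1)
  lam <- eigen(r5, symmetric = TRUE)$values
  oracle <- sum(ifelse(lam >= 1, 1, 0) + (lam - floor(lam)))
  expect_equal(got, oracle, tolerance = 1e-10)
  expect_lte(got, k)
})

test_that("Fisher's combined p reproduces published gene-level values", {
  tab <- readr::read_tsv(fixture_path("endometriosis_migraine_gene_fcp.tsv"),
                         show_col_types = FALSE)
  fcp <- fisher_combined(tab$gene_p_endometriosis, tab$gene_p_migraine)
  expect_equal(signif(fcp, 3), tab$fcp_published)
  expect_equal(fisher_combined(1, 1), 1)
  expect_equal(fisher_combined(0.3, 0.7), fisher_combined(0.7, 0.3))
  expect_true(fisher_combined(0.01, 0.5) < fisher_combined(0.02, 0.5))
  expect_error(fisher_combined(0, 0.5), "must be > 0")
})

test_that("the exact binomial overlap tail matches direct pmf summation", {
  expect_equal(overlap_binomial_test(0, 10, 0.3), 1)
  oracle <- sum(vapply(3:10, function(k) {
    choose(10, k) * 0.1^k * 0.9^(10 - k)
  }, numeric(1)))
  expect_equal(overlap_binomial_test(3, 10, 0.1), oracle,
               tolerance = 1e-12)
  ks <- 0:6
  ps <- vapply(ks, overlap_binomial_test, numeric(1), n = 20, p0 = 0.2)
  expect_true(all(diff(ps) < 0))
})

test_that("the Bonferroni gene threshold is 0.05 over the effective count", {
  expect_equal(signif(genomewide_threshold(17104), 3), 2.92e-6)
  expect_equal(genomewide_threshold(50), 1e-3)
  expect_equal(genomewide_threshold(1), 0.05)
  expect_error(genomewide_threshold(0), "me_total")
})

test_that("gene tables and overlap results satisfy their invariants", {
  m <- 600
  cfg <- synth_config(m_snps = m, n1 = 20000, n2 = 20000, h2_1 = 0.4,
                      h2_2 = 0.4, rg = 0.8)
  ld <- gen_ld_reference(m, 20, 0.6)
  sim <- gen_joint_sumstats(cfg, ld, seed = 91)
  ann <- gen_gene_annotation(m, 30, seed = 92)
  g1 <- suppressMessages(gene_pvalues(sim$stats1, ann, ld,
                                      n_sim_max = 2000, seed = 93))
  g2 <- suppressMessages(gene_pvalues(sim$stats2, ann, ld,
                                      n_sim_max = 2000, seed = 94))
  expect_equal(nrow(g1), 30)
  expect_true(all(g1$gene_p >= g1$top_snp_p - 0.05))
  expect_true(all(g1$start <= g1$stop))
  me <- effective_genes(g1, ld)
  expect_lte(me, nrow(g1))

  res <- overlap_binomial(g1, g2, 0.5, ld)
  expect_lte(res$raw_overlap, min(res$raw_discovery, res$raw_target))
  expect_true(res$expected_prop >= 0 && res$expected_prop <= 1)
  expect_true(res$observed_prop >= 0 && res$observed_prop <= 1)
  expect_true(res$p_binomial >= 0 && res$p_binomial <= 1)

  comb <- combine_genes(g1, g2, p_max = 1.1)
  expect_equal(nrow(comb), 30)
  expect_true(all(comb$fcp <= 1))
})
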