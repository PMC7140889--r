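# brute-force oracle for a cell: filter and count directly
cell_oracle <- function(pair, ids, t1, t2) {
  sub <- pair[pair$snp_id %in% ids & pair$p_1 <= t1 & pair$p_2 <= t2, ]
  conc <- sign(sub$beta_1) == sign(sub$beta_2)
  c(n = nrow(sub), conc = sum(conc))
}

test_that("grid cells agree with a direct filter-and-count oracle", {
  pair <- make_pair(400, seed = 2, rho_sign = 0.3)
  ids <- pair$snp_id
  grid <- build_grid(pair, ids)
  expect_equal(nrow(grid), 144)
  for (cell in list(c(0.01, 0.01), c(0.05, 0.2), c(0.5, 0.1), c(1, 1))) {
    o <- cell_oracle(pair, ids, cell[1], cell[2])
    row <- grid[grid$p1_cutoff == cell[1] & grid$p2_cutoff == cell[2], ]
    expect_equal(row$n_snps, unname(o["n"]))
    expect_equal(row$n_concordant, unname(o["conc"]))
  }
  expect_equal(grid$n_concordant + grid$n_discordant, grid$n_snps)
})

test_that("uniformly positive effects give fully concordant cells", {
  pair <- make_pair(100, seed = 3)
  pair$beta_1 <- abs(pair$beta_1)
  pair$beta_2 <- abs(pair$beta_2)
  grid <- build_grid(pair, pair$snp_id)
  expect_true(all(grid$prop_concordant[grid$n_snps > 0] == 1))
})

test_that("cell counts are non-decreasing in both cutoffs", {
  pair <- make_pair(500, seed = 4)
  grid <- build_grid(pair, pair$snp_id)
  n <- matrix(grid$n_snps, 12, 12)  # rows: p1 cutoffs, cols: p2 cutoffs
  expect_true(all(apply(n, 2, diff) >= 0))
  expect_true(all(apply(n, 1, diff) >= 0))
  diag_cells <- grid[grid$p1_cutoff == grid$p2_cutoff, ]
  expect_lte(diag_cells$n_snps[diag_cells$p1_cutoff == 0.05],
             diag_cells$n_snps[diag_cells$p1_cutoff == 0.1])
})

test_that("zero-effect SNPs are excluded from concordance counting", {
  pair <- make_pair(50, seed = 5)
  pair$beta_1[1:5] <- 0
  expect_message(grid <- build_grid(pair, pair$snp_id), "zero effect")
  expect_equal(grid$n_snps[grid$p1_cutoff == 1 & grid$p2_cutoff == 1], 45)
})

test_that("the in-package Fisher test matches enumeration and stats::fisher.test", {
  # balanced table: exact independence
  ft <- fisher_exact_2x2(5, 5, 5, 5)
  expect_equal(ft$or, 1)
  expect_equal(ft$p, 1)

  # brute-force hypergeometric oracle for [[6,1],[2,7]]
  brute_p <- function(n11, n12, n21, n22) {
    r1 <- n11 + n12; c1 <- n11 + n21; N <- n11 + n12 + n21 + n22
    support <- max(0, c1 - (N - r1)):min(r1, c1)
    pr <- vapply(support, function(k) {
      choose(r1, k) * choose(N - r1, c1 - k) / choose(N, c1)
    }, numeric(1))
    obs <- pr[support == n11]
    sum(pr[pr <= obs * (1 + 1e-7)])
  }
  got <- fisher_exact_2x2(6, 1, 2, 7)
  expect_equal(got$p, brute_p(6, 1, 2, 7), tolerance = 1e-12)
  expect_equal(got$or, (6 * 7) / (1 * 2))

  # random tables against the reference implementation
  set.seed(8)
  for (i in 1:20) {
    tb <- matrix(rpois(4, 6), 2)
    got <- fisher_exact_2x2(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
    ref <- stats::fisher.test(tb)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }

  # degenerate margin
  expect_equal(fisher_exact_2x2(3, 0, 4, 0)$p, 1)
  expect_true(is.na(fisher_exact_2x2(3, 0, 4, 0)$or))
})

test_that("concordance proportions follow printed-count arithmetic", {
  # a cell holding 1383 SNPs of which 804 concordant reports 804/1383
  n_conc <- 804
  n_disc <- 1383 - 804
  pair <- make_pair(1383, seed = 6)
  s1 <- sign(pair$beta_1)
  pair$beta_2 <- abs(pair$beta_2) *
    s1 * c(rep(1, n_conc), rep(-1, n_disc))
  grid <- build_grid(pair, pair$snp_id)
  cell <- grid[grid$p1_cutoff == 1 & grid$p2_cutoff == 1, ]
  expect_equal(cell$n_concordant, n_conc)
  expect_equal(round(cell$prop_concordant, 2), 0.58)
})

test_that("binomial subset test counts and tails behave", {
  pair <- make_pair(300, seed = 7)
  grid <- concordance_test(build_grid(pair, pair$snp_id))
  bt <- binomial_subset_test(grid)
  expect_equal(bt$n_cells, 144)
  # exhaustive pmf-sum oracle at count = 10
  pmf_tail <- sum(vapply(10:144, function(k) {
    choose(144, k) * 0.025^k * 0.975^(144 - k)
  }, numeric(1)))
  expect_equal(stats::pbinom(9, 144, 0.025, lower.tail = FALSE), pmf_tail,
               tolerance = 1e-12)
  # boundary counts
  expect_equal(stats::pbinom(-1, 144, 0.025, lower.tail = FALSE), 1)
  expect_equal(stats::pbinom(143, 144, 0.025, lower.tail = FALSE),
               0.025^144)
})

test_that("permutation p-values follow the add-one formula and its floor", {
  pair <- make_pair(200, seed = 8, rho_sign = 0.6)
  res <- permutation_null(pair, pair$snp_id, n_perm = 19, seed = 1)
  expect_gte(res$p_fsig_permuted, 1 / 20)
  expect_gte(res$p_ftmin_permuted, 1 / 20)
  expect_lte(res$p_fsig_permuted, 1)
  # n_perm = 1: p is 1/2 when the permutation is less extreme, else 1
  res1 <- permutation_null(pair, pair$snp_id, n_perm = 1, seed = 2)
  expect_true(res1$p_fsig_permuted %in% c(0.5, 1))
})

test_that("swapping dataset order transposes the grid", {
  pair <- make_pair(300, seed = 9, rho_sign = 0.2)
  swapped <- pair
  names(swapped)[match(c("beta_1", "se_1", "p_1", "n_1"), names(swapped))] <-
    c("beta_x", "se_x", "p_x", "n_x")
  names(swapped)[match(c("beta_2", "se_2", "p_2", "n_2"), names(swapped))] <-
    c("beta_1", "se_1", "p_1", "n_1")
  names(swapped)[match(c("beta_x", "se_x", "p_x", "n_x"), names(swapped))] <-
    c("beta_2", "se_2", "p_2", "n_2")
  g1 <- build_grid(pair, pair$snp_id)
  g2 <- build_grid(swapped, swapped$snp_id)
  m1 <- matrix(g1$n_concordant, 12, 12)
  m2 <- matrix(g2$n_concordant, 12, 12)
  expect_equal(m1, t(m2))
  full1 <- g1[g1$p1_cutoff == 1 & g1$p2_cutoff == 1, ]
  full2 <- g2[g2$p1_cutoff == 1 & g2$p2_cutoff == 1, ]
  expect_equal(full1$n_snps, full2$n_snps)
  expect_equal(full1$n_concordant, full2$n_concordant)
})

test_that("under a sign-symmetric null the concordance proportion is 1/2", {
  props <- vapply(1:20, function(s) {
    pair <- make_pair(500, seed = 100 + s, rho_sign = 0)
    grid <- build_grid(pair, pair$snp_id)
    grid$prop_concordant[grid$p1_cutoff == 1 & grid$p2_cutoff == 1]
  }, numeric(1))
  expect_lt(abs(mean(props) - 0.5), 3 * sqrt(0.25 / (500 * 20)))
})
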