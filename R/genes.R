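#' Assign SNPs to genes by position
#'
#' A SNP belongs to a gene iff `start - padding <= pos <= stop + padding`
#' (1-based inclusive coordinates on both sides; padding 0 is the
#' "+/- 0 kb outside gene" convention). Genes containing no SNPs are
#' dropped and counted; malformed annotation rows (missing fields or
#' `start > stop`) are dropped with a warning.
#'
#' @param stats A summary-statistics tibble (`snp_id`, `chrom`, `pos`,
#'   `pvalue` used).
#' @param annotation A tibble with columns `chrom`, `start`, `stop`,
#'   `gene`.
#' @param padding Base pairs added to each side of every gene (default 0).
#' @return A tibble with one row per (gene, SNP) pair: `gene`, `chrom`,
#'   `start`, `stop`, `snp_id`, `pos`, `pvalue`.
#' @export
assign_snps_to_genes <- function(stats, annotation, padding = 0) {
  ann <- as_tibble(annotation)
  bad <- is.na(ann$chrom) | is.na(ann$start) | is.na(ann$stop) |
    is.na(ann$gene) | ann$start > ann$stop
  if (any(bad)) {
    warn(sprintf("Dropped %d malformed annotation row(s).", sum(bad)))
    ann <- ann[!bad, ]
  }
  ann$.start_pad <- ann$start - padding
  ann$.stop_pad <- ann$stop + padding
  ann$chrom <- as.character(ann$chrom)
  snp <- stats[, c("snp_id", "chrom", "pos", "pvalue")]
  snp$chrom <- as.character(snp$chrom)
  hits <- inner_join(
    ann, snp,
    by = join_by(chrom, .start_pad <= pos, .stop_pad >= pos))
  n_empty <- sum(!ann$gene %in% hits$gene)
  if (n_empty > 0) {
    inform(sprintf("%d gene(s) contain no SNPs and were dropped.", n_empty))
  }
  hits[, c("gene", "chrom", "start", "stop", "snp_id", "pos", "pvalue")]
}

# nearest-PSD repair: clip negative eigenvalues, restore unit diagonal
nearest_psd <- function(r) {
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) >= -1e-10) return(r)
  inform("LD submatrix repaired to nearest positive semi-definite form.")
  v <- pmax(e$values, 1e-10)
  r2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(r2))
  r2 <- r2 / outer(d, d)
  (r2 + t(r2)) / 2
}

#' Best-SNP gene-based association test
#'
#' The gene statistic is the smallest SNP p-value in the gene; its
#' significance is calibrated by simulating z-scores from the multivariate
#' normal null with the gene's LD correlation matrix, converting to
#' two-sided p-values and minimising. The empirical p-value uses the
#' add-one formula `(1 + #{simulated min <= observed}) / (n_sim + 1)` and
#' the simulation count escalates (1e3, 1e4, ...) until at least 10
#' exceedances are seen or `n_sim_max` is reached, so small p-values get
#' proportionally more precision.
#'
#' @param p Vector of SNP p-values in the gene.
#' @param r LD correlation matrix for those SNPs (repaired to the nearest
#'   positive semi-definite matrix if needed).
#' @param n_sim_max Simulation cap (default 1e5).
#' @param n_sim_min Simulations always performed before the escalation rule
#'   may stop (default 1000; raise it when a fixed Monte Carlo precision is
#'   needed).
#' @param seed Integer RNG seed.
#' @return The gene p-value (scalar).
#' @export
best_snp_test <- function(p, r, n_sim_max = 1e5, n_sim_min = 1000, seed) {
  m <- length(p)
  stopifnot(m >= 1, all(dim(as.matrix(r)) == c(m, m)))
  obs <- min(p)
  set.seed(seed)
  if (m == 1L) {
    U <- matrix(1, 1, 1)
  } else {
    r <- nearest_psd(as.matrix(r))
    U <- chol(r + diag(1e-10, m))
  }
  n_done <- 0
  n_exceed <- 0
  n_next <- max(1000, min(n_sim_min, n_sim_max))
  while (TRUE) {
    draw <- min(n_next, n_sim_max - n_done)
    z <- matrix(rnorm(draw * m), draw, m) %*% U
    pv <- two_sided_p(z)
    sim_min <- pv[cbind(seq_len(draw), max.col(-pv, ties.method = "first"))]
    n_exceed <- n_exceed + sum(sim_min <= obs)
    n_done <- n_done + draw
    if (n_exceed >= 10 || n_done >= n_sim_max) break
    n_next <- n_done * 9  # escalate to the next power of ten
  }
  (1 + n_exceed) / (n_done + 1)
}

#' Gene-based p-values for a whole summary-statistics table
#'
#' Maps SNPs to genes, runs the Best-SNP test per gene using the gene's LD
#' submatrix, and reports the per-gene top SNP.
#'
#' @inheritParams assign_snps_to_genes
#' @param ld An `ld_ref`.
#' @param n_sim_max Per-gene simulation cap (default 1e5).
#' @param seed Integer RNG seed (each gene gets a derived seed).
#' @return A tibble of class `gene_table`: `gene`, `chrom`, `start`,
#'   `stop`, `n_snps`, `top_snp`, `top_snp_p`, `gene_p`.
#' @export
gene_pvalues <- function(stats, annotation, ld, n_sim_max = 1e5, seed,
                         padding = 0) {
  map <- assign_snps_to_genes(stats, annotation, padding = padding)
  genes <- split(map, map$gene)
  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[[i]]
    top <- which.min(g$pvalue)
    r <- ld_submatrix(ld, g$snp_id)
    gp <- best_snp_test(g$pvalue, r, n_sim_max = n_sim_max,
                        seed = seed + i)
    tibble(gene = g$gene[1], chrom = g$chrom[1], start = g$start[1],
           stop = g$stop[1], n_snps = nrow(g),
           top_snp = g$snp_id[top], top_snp_p = g$pvalue[top],
           gene_p = gp)
  })
  out <- arrange(bind_rows(rows), chrom, start)
  structure(out, class = c("gene_table", class(out)))
}

#' Effective number of independent genes
#'
#' The gene-based tests of neighbouring genes are correlated through LD
#' between their top SNPs. Top SNPs are partitioned into blocks assumed
#' independent (chains of pairwise r-squared >= `r2_thresh`, within LD
#' blocks only), and within each block the Li-Ji eigenvalue rule converts
#' the top-SNP correlation matrix into an effective test count:
#' `Me_block = sum(I(lambda >= 1) + (lambda - floor(lambda)))`. The total
#' effective number is the sum over blocks; under identity LD it equals
#' the gene count exactly.
#'
#' @param gene_table A `gene_table` (or any tibble with a `top_snp`
#'   column).
#' @param ld An `ld_ref`.
#' @param r2_thresh Independence threshold (default 0.1).
#' @return The effective number of independent genes (scalar).
#' @export
effective_genes <- function(gene_table, ld, r2_thresh = 0.1) {
  ids <- gene_table$top_snp
  if (length(ids) == 0L) return(0)
  r <- ld_submatrix(ld, ids)
  # connected components of the |r|^2 >= threshold graph
  adj <- r^2 >= r2_thresh
  n <- length(ids)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      frontier <- i
      comp[i] <- cur
      while (length(frontier) > 0) {
        nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0L)
        comp[nb] <- cur
        frontier <- nb
      }
    }
  }
  me <- 0
  for (g in seq_len(cur)) {
    sel <- which(comp == g)
    if (length(sel) == 1L) {
      me <- me + 1
    } else {
      lam <- eigen(r[sel, sel], symmetric = TRUE, only.values = TRUE)$values
      lam <- pmax(lam, 0)
      me <- me + sum((lam >= 1) + (lam - floor(lam)))
    }
  }
  me
}

#' Fisher's combined p-value across two traits
#'
#' `fcp = P(chi2_4 >= -2 (ln p1 + ln p2))`: the upper chi-square tail with
#' 4 degrees of freedom. Symmetric in its arguments and strictly
#' decreasing in each; equals 1 iff both inputs are 1.
#'
#' @param p1,p2 P-values in (0, 1] (vectorised).
#' @return Combined p-values.
#' @export
fisher_combined <- function(p1, p2) {
  if (any(p1 <= 0) || any(p2 <= 0)) abort("P-values must be > 0.")
  stats::pchisq(-2 * (log(p1) + log(p2)), df = 4, lower.tail = FALSE)
}

#' Combine gene-based results across two traits
#'
#' Joins two gene tables on the gene symbol, restricts to genes with both
#' p-values below `p_max`, and attaches Fisher's combined p-value.
#'
#' @param tab1,tab2 `gene_table` tibbles for the two traits.
#' @param p_max Per-trait inclusion threshold (default 0.1).
#' @return A tibble with `gene`, `p_trait1`, `p_trait2`, `fcp`, sorted by
#'   `fcp`.
#' @export
combine_genes <- function(tab1, tab2, p_max = 0.1) {
  j <- inner_join(
    tibble(gene = tab1$gene, p_trait1 = tab1$gene_p),
    tibble(gene = tab2$gene, p_trait2 = tab2$gene_p),
    by = "gene")
  j <- j[j$p_trait1 < p_max & j$p_trait2 < p_max, ]
  j$fcp <- fisher_combined(j$p_trait1, j$p_trait2)
  arrange(j, .data$fcp)
}

#' One-sided exact binomial tail
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`, by exact tail summation.
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p0 Null success probability.
#' @return The upper-tail probability.
#' @export
overlap_binomial_test <- function(k, n, p0) {
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Exact binomial test for gene-level overlap between two traits
#'
#' Tests whether more genes fall below the significance threshold in both
#' the discovery and the target trait than expected by chance, on the
#' scale of effective (LD-independent) gene counts. The expected overlap
#' proportion is the target's effective significant count over its total
#' effective count; the observed count is the effective number of
#' overlapping genes (the raw overlap scaled by the discovery set's
#' effective/raw ratio, rounded to an integer); the p-value is the
#' one-sided exact binomial tail over the discovery's effective
#' significant count.
#'
#' @param discovery,target `gene_table` tibbles for the two traits.
#' @param threshold Gene p-value threshold (e.g. 0.1, 0.05, 0.01).
#' @param ld An `ld_ref` used for the effective counts.
#' @return A tibble of class `overlap_result` with the raw and effective
#'   counts, expected and observed proportions and the binomial p-value;
#'   `NA` p-value when the discovery has no significant genes.
#' @export
overlap_binomial <- function(discovery, target, threshold, ld) {
  disc_sig <- discovery[discovery$gene_p < threshold, ]
  targ_sig <- target[target$gene_p < threshold, ]
  raw_overlap <- length(intersect(disc_sig$gene, targ_sig$gene))
  eff_target_total <- effective_genes(target, ld)
  eff_disc_sig <- round(effective_genes(disc_sig, ld))
  eff_targ_sig <- round(effective_genes(targ_sig, ld))
  eff_overlap <- if (nrow(disc_sig) > 0) {
    round(raw_overlap * effective_genes(disc_sig, ld) / nrow(disc_sig))
  } else 0
  p0 <- eff_targ_sig / eff_target_total
  res <- tibble(
    threshold = threshold,
    raw_discovery = nrow(disc_sig), eff_discovery = eff_disc_sig,
    raw_target = nrow(targ_sig), eff_target = eff_targ_sig,
    eff_target_total = eff_target_total,
    raw_overlap = raw_overlap, eff_overlap = eff_overlap,
    expected_prop = p0,
    observed_prop = if (eff_disc_sig > 0) eff_overlap / eff_disc_sig
    else NA_real_,
    p_binomial = if (eff_disc_sig > 0) {
      overlap_binomial_test(eff_overlap, eff_disc_sig, p0)
    } else NA_real_)
  structure(res, class = c("overlap_result", class(res)))
}

#' Bonferroni genome-wide gene-based threshold
#'
#' `0.05 / Me` for `Me` effective independent genes.
#'
#' @param me_total Effective number of independent genes (> 0).
#' @return The genome-wide gene-based significance threshold.
#' @export
genomewide_threshold <- function(me_total) {
  check_number(me_total, "me_total", lower = 0, closed_lower = FALSE)
  0.05 / me_total
}
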