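#' Default pipeline configuration
#'
#' Returns the full default configuration for [run_pipeline()] as a nested
#' list; user-supplied values (from a list or a YAML file) are merged over
#' it. Defaults mirror the analysis settings used throughout the package:
#' genome-wide threshold 5e-8, suggestive 1e-5, MR clumping r2 0.001, SECA
#' clumping r2 0.1 with 1000 permutations, gene-overlap thresholds
#' 0.01/0.05/0.1, term sizes 5-350.
#'
#' @return A nested list.
#' @export
pipeline_defaults <- function() {
  list(
    data = list(sumstats1 = NULL, sumstats2 = NULL, ld = NULL,
                annotation = NULL, gene_sets = NULL),
    simulate = NULL,
    seeds = list(simulate = 1L, seca = 2L, mr = 3L, genes = 4L),
    seca = list(r2_max = 0.1, n_perm = 1000),
    ldsc = list(sample_prev1 = NULL, pop_prev1 = NULL,
                sample_prev2 = NULL, pop_prev2 = NULL,
                constrain_i1 = NULL, constrain_i2 = NULL,
                constrain_gencov = TRUE, n_blocks = 200),
    meta = list(gw_p = 5e-8, suggestive_p = 1e-5, model = "re2"),
    mr = list(p_thresh = 5e-8, clump_r2 = 0.001, n_boot = 1000),
    genes = list(n_sim_max = 1e4, thresholds = c(0.01, 0.05, 0.1),
                 fcp_p_max = 0.1),
    enrichment = list(min_size = 5, max_size = 350, adjust = "BH"))
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$simulate)) {
    for (f in c("sumstats1", "sumstats2", "ld")) {
      p <- cfg$data[[f]]
      if (is.null(p)) {
        abort(sprintf("Config error: `data$%s` is required unless `simulate` is set.", f))
      }
      if (!identical(p, "independent") && !file.exists(p) && !dir.exists(p)) {
        abort(sprintf("Config error: `data$%s` path '%s' does not exist.", f, p))
      }
    }
  }
  for (s in c("simulate", "seca", "mr", "genes")) {
    if (is.null(cfg$seeds[[s]])) {
      abort(sprintf("Config error: seed `%s` is missing.", s))
    }
  }
  invisible(cfg)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)), parent = e)
  })
}

#' Run the full cross-trait comorbidity pipeline
#'
#' Orchestrates the whole analysis from a single configuration:
#' harmonization and clumping, SECA, LD score regression (heritability and
#' genetic correlation), cross-disorder meta-analysis, two-sample MR in
#' the exposure-to-outcome direction, gene-based tests with Fisher
#' combined p-values and overlap binomial tests, and gene-set enrichment
#' of the overlapping genes. Each stage writes its table under `out_dir`
#' and a consolidated summary is written as JSON; a stage failure halts
#' the run with the stage named, preserving earlier outputs. Given the
#' same inputs and seeds the outputs are byte-identical across runs.
#'
#' When `simulate` is configured, inputs are generated by the package's
#' synthetic-data module instead of read from disk.
#'
#' @param config A nested list, or the path to a YAML file, merged over
#'   [pipeline_defaults()].
#' @param out_dir Output directory (created if needed).
#' @return A list of class `pipeline_report` with one element per stage.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(pipeline_defaults(), config)
  validate_pipeline_config(cfg)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tsv <- function(x, name) {
    readr::write_tsv(x, file.path(out_dir, paste0(name, ".tsv")),
                     progress = FALSE)
    x
  }

  inputs <- run_stage("inputs", {
    if (!is.null(cfg$simulate)) {
      sc <- do.call(synth_config, cfg$simulate[
        intersect(names(cfg$simulate), names(formals(synth_config)))])
      ld <- gen_ld_reference(sc$m_snps, sc$block_size, sc$rho)
      sim <- gen_joint_sumstats(sc, ld, seed = cfg$seeds$simulate)
      n_genes <- cfg$simulate$n_genes %||% max(10, sc$m_snps %/% 100)
      ann <- gen_gene_annotation(sc$m_snps, n_genes,
                                 seed = cfg$seeds$simulate + 1)
      gmt <- gen_gene_sets(ann$gene, cfg$simulate$n_terms %||% 50,
                           size_range = c(min(5, n_genes),
                                          min(50, n_genes)),
                           seed = cfg$seeds$simulate + 2)
      list(s1 = sim$stats1, s2 = sim$stats2, ld = ld, annotation = ann,
           gene_sets = gmt, truth = sim$truth)
    } else {
      s1 <- read_sumstats(cfg$data$sumstats1)
      s2 <- read_sumstats(cfg$data$sumstats2)
      ld <- if (identical(cfg$data$ld, "independent")) {
        ld_independent(union(s1$snp_id, s2$snp_id))
      } else read_ld_reference(cfg$data$ld)
      ann <- if (!is.null(cfg$data$annotation)) {
        readr::read_tsv(cfg$data$annotation, show_col_types = FALSE,
                        progress = FALSE)
      } else NULL
      gmt <- if (!is.null(cfg$data$gene_sets)) {
        read_gmt(cfg$data$gene_sets)
      } else NULL
      list(s1 = s1, s2 = s2, ld = ld, annotation = ann, gene_sets = gmt)
    }
  })

  pair <- run_stage("harmonize", {
    p <- harmonize_pair(inputs$s1, inputs$s2)
    tsv(as_tibble(p), "harmonized")
    p
  })

  seca_res <- run_stage("seca", {
    r <- seca(pair, inputs$ld, r2_max = cfg$seca$r2_max,
              n_perm = cfg$seca$n_perm, seed = cfg$seeds$seca)
    tsv(tidy(r), "seca_grid")
    r
  })

  ldsc_res <- run_stage("ldsc", {
    ls <- compute_ld_scores(inputs$ld)
    h2_1 <- fit_h2(inputs$s1, ls,
                   constrain_intercept = cfg$ldsc$constrain_i1,
                   sample_prev = cfg$ldsc$sample_prev1,
                   pop_prev = cfg$ldsc$pop_prev1,
                   n_blocks = cfg$ldsc$n_blocks)
    h2_2 <- fit_h2(inputs$s2, ls,
                   constrain_intercept = cfg$ldsc$constrain_i2,
                   sample_prev = cfg$ldsc$sample_prev2,
                   pop_prev = cfg$ldsc$pop_prev2,
                   n_blocks = cfg$ldsc$n_blocks)
    rg <- fit_rg(inputs$s1, inputs$s2, ls,
                 constrain_i1 = cfg$ldsc$constrain_i1,
                 constrain_i2 = cfg$ldsc$constrain_i2,
                 constrain_gencov = cfg$ldsc$constrain_gencov,
                 n_blocks = cfg$ldsc$n_blocks)
    tsv(bind_rows(h2_trait1 = tidy(h2_1), h2_trait2 = tidy(h2_2),
                  rg = tidy(rg), .id = "fit"), "ldsc")
    list(h2_1 = h2_1, h2_2 = h2_2, rg = rg)
  })

  meta_res <- run_stage("meta", {
    rows <- meta_analyse(pair, gw_p = cfg$meta$gw_p,
                         suggestive_p = cfg$meta$suggestive_p)
    tsv(rows, "meta")
    loci <- classify_loci(rows, inputs$ld, model = cfg$meta$model,
                          gw_p = cfg$meta$gw_p,
                          suggestive_p = cfg$meta$suggestive_p)
    tsv(select(loci, -all_of(genes_list_col(loci))), "meta_loci")
    list(rows = rows, loci = loci)
  })

  mr_res <- run_stage("mr", {
    iv <- select_instruments(inputs$s1, inputs$s2, inputs$ld,
                             p_thresh = cfg$mr$p_thresh,
                             r2_max = cfg$mr$clump_r2)
    tsv(as_tibble(iv), "mr_instruments")
    fits <- mr_all(iv, seed = cfg$seeds$mr, n_boot = cfg$mr$n_boot)
    tsv(fits, "mr_estimates")
    loo <- mr_leave_one_out(iv)
    tsv(loo, "mr_leave_one_out")
    list(instruments = iv, fits = fits, leave_one_out = loo,
         heterogeneity = attr(fits, "heterogeneity"),
         egger_intercept = attr(fits, "egger_intercept"))
  })

  genes_res <- run_stage("genes", {
    if (is.null(inputs$annotation)) {
      NULL
    } else {
      g1 <- gene_pvalues(inputs$s1, inputs$annotation, inputs$ld,
                         n_sim_max = cfg$genes$n_sim_max,
                         seed = cfg$seeds$genes)
      g2 <- gene_pvalues(inputs$s2, inputs$annotation, inputs$ld,
                         n_sim_max = cfg$genes$n_sim_max,
                         seed = cfg$seeds$genes + 100000)
      tsv(g1, "genes_trait1")
      tsv(g2, "genes_trait2")
      combined <- combine_genes(g1, g2, p_max = cfg$genes$fcp_p_max)
      tsv(combined, "genes_combined")
      me <- max(effective_genes(g1, inputs$ld),
                effective_genes(g2, inputs$ld))
      overlaps <- bind_rows(lapply(cfg$genes$thresholds, function(th) {
        overlap_binomial(g1, g2, th, inputs$ld)
      }))
      tsv(overlaps, "genes_overlap")
      list(trait1 = g1, trait2 = g2, combined = combined,
           me_total = me, gw_threshold = genomewide_threshold(me),
           overlap = overlaps)
    }
  })

  enrich_res <- run_stage("enrichment", {
    if (is.null(genes_res) || is.null(inputs$gene_sets)) {
      NULL
    } else {
      overlapping <- genes_res$combined$gene
      if (length(overlapping) == 0) {
        NULL
      } else {
        e <- enrich(overlapping, inputs$gene_sets,
                    background = genes_res$trait1$gene,
                    min_size = cfg$enrichment$min_size,
                    max_size = cfg$enrichment$max_size,
                    adjust = cfg$enrichment$adjust)
        tsv(select(e, -"overlap_genes"), "enrichment")
        e
      }
    }
  })

  report <- list(
    config = cfg,
    harmonization = attr(pair, "harmonization"),
    seca = glance(seca_res),
    ldsc = list(h2_trait1 = glance(ldsc_res$h2_1),
                h2_trait2 = glance(ldsc_res$h2_2),
                rg = glance(ldsc_res$rg)),
    meta = list(n_genomewide = sum(meta_res$rows$class_re2 == "genome-wide"),
                n_suggestive = sum(meta_res$rows$class_re2 == "suggestive"),
                loci = meta_res$loci),
    mr = mr_res[c("fits", "heterogeneity", "egger_intercept")],
    genes = if (!is.null(genes_res)) {
      list(me_total = genes_res$me_total,
           gw_threshold = genes_res$gw_threshold,
           n_combined_gw = sum(genes_res$combined$fcp <
                                 genes_res$gw_threshold),
           overlap = genes_res$overlap)
    },
    enrichment = if (!is.null(enrich_res)) {
      list(n_significant = sum(enrich_res$significant))
    })
  summary_json <- list(
    seca = as.list(report$seca),
    ldsc = lapply(report$ldsc, as.list),
    meta = report$meta[c("n_genomewide", "n_suggestive")],
    mr = list(estimates = report$mr$fits),
    genes = if (!is.null(report$genes)) {
      report$genes[c("me_total", "gw_threshold", "n_combined_gw")]
    },
    enrichment = report$enrichment)
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(c(report, list(out_dir = out_dir,
                           stages = list(pair = pair, seca = seca_res,
                                         ldsc = ldsc_res, meta = meta_res,
                                         mr = mr_res, genes = genes_res,
                                         enrichment = enrich_res))),
            class = "pipeline_report")
}

genes_list_col <- function(x) {
  names(x)[vapply(x, is.list, TRUE)]
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  outputs in: %s\n", x$out_dir))
  cat(sprintf("  SECA: %d significant subsets (perm p = %.3g)\n",
              x$seca$n_sig_subsets, x$seca$p_fsig_permuted))
  cat(sprintf("  LDSC: rg = %.3f (p = %.3g)\n", x$ldsc$rg$rg,
              x$ldsc$rg$rg_p))
  cat(sprintf("  meta: %d genome-wide, %d suggestive SNPs (RE2)\n",
              x$meta$n_genomewide, x$meta$n_suggestive))
  ivw <- x$mr$fits[x$mr$fits$method == "ivw_multiplicative_re", ]
  cat(sprintf("  MR IVW: OR = %.3f (p = %.3g)\n", ivw$or, ivw$p.value))
  if (!is.null(x$genes)) {
    cat(sprintf("  genes: Me = %.0f, threshold = %.3g, %d combined genome-wide\n",
                x$genes$me_total, x$genes$gw_threshold,
                x$genes$n_combined_gw))
  }
  invisible(x)
}
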