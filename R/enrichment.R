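#' Read a GMT gene-set file
#'
#' GMT dialect: one term per line, tab-separated — term ID, description,
#' then member gene symbols. Duplicate members within a term are
#' deduplicated; malformed lines (fewer than two fields) are skipped with a
#' warning. Terms with zero members are retained (they are removed later by
#' the size filter in [enrich()]).
#'
#' @param path Path to the GMT file.
#' @return A tibble with columns `term_id`, `term_name`, `genes`
#'   (list-column of character vectors) and `term_size`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 2
  if (any(!ok)) {
    warn(sprintf("Skipped %d malformed GMT line(s).", sum(!ok)))
    parts <- parts[ok]
  }
  if (length(parts) == 0L) abort("No parseable GMT terms.")
  tb <- tibble(
    term_id = vapply(parts, `[[`, "", 1),
    term_name = vapply(parts, `[[`, "", 2),
    genes = lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])])))
  if (anyDuplicated(tb$term_id)) abort("Duplicate term IDs in GMT file.")
  tb$term_size <- lengths(tb$genes)
  tb
}

#' Write gene sets to a GMT file
#'
#' @param db A gene-set tibble (`term_id`, `term_name`, `genes`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(seq_len(nrow(db)), function(i) {
    paste(c(db$term_id[i], db$term_name[i], db$genes[[i]]), collapse = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Over-representation analysis of a gene list
#'
#' Hypergeometric upper-tail test per term: with `N` background genes, `K`
#' of them in the term, and a query of `n` genes of which `k` hit the term,
#' `p = P(X >= k)` for `X ~ Hypergeometric(K, N - K, n)`. Terms are
#' intersected with the background and filtered to sizes within
#' `[min_size, max_size]` before testing; query genes outside the
#' background are dropped with a message. P-values are adjusted over the
#' tested terms (Benjamini-Hochberg by default; any [stats::p.adjust()]
#' method is accepted).
#'
#' @param query Character vector of gene symbols.
#' @param db Gene-set tibble from [read_gmt()] or [gen_gene_sets()].
#' @param background Character vector: the gene universe.
#' @param min_size,max_size Term-size bounds after background intersection
#'   (defaults 5 and 350).
#' @param adjust Multiple-testing adjustment method (default `"BH"`).
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @return A tibble of class `enrichment_result`, sorted by adjusted
#'   p-value, with `term_id`, `term_name`, `k_overlap`, `term_size`
#'   (`K`), `query_size` (`n`), `background_size` (`N`), `p_hyper`,
#'   `p_adj`, `significant`, `overlap_genes` (list-column).
#' @export
enrich <- function(query, db, background, min_size = 5, max_size = 350,
                   adjust = "BH", alpha = 0.05) {
  background <- unique(background)
  query <- unique(query)
  outside <- setdiff(query, background)
  if (length(outside) > 0) {
    inform(sprintf("%d query gene(s) outside the background; dropped.",
                   length(outside)))
    query <- intersect(query, background)
  }
  if (length(query) == 0L) {
    abort("Empty query after intersecting with the background.")
  }
  members <- lapply(db$genes, intersect, background)
  sizes <- lengths(members)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) abort("No terms remain after the size filter.")
  members <- members[keep]
  N <- length(background)
  n <- length(query)
  k <- vapply(members, function(g) length(intersect(g, query)), 1L)
  K <- lengths(members)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- tibble(
    term_id = db$term_id[keep], term_name = db$term_name[keep],
    k_overlap = k, term_size = K, query_size = n, background_size = N,
    p_hyper = p, p_adj = stats::p.adjust(p, method = adjust),
    overlap_genes = lapply(members, intersect, query))
  out$significant <- out$p_adj < alpha
  out <- arrange(out, .data$p_adj, .data$p_hyper)
  structure(out, class = c("enrichment_result", class(out)))
}
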