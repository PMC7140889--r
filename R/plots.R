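#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_text
#'   geom_abline geom_errorbar geom_errorbarh geom_vline geom_hline labs
#'   scale_fill_gradient2 theme_minimal
#' @export
ggplot2::autoplot

#' Heatmap of the SECA concordance grid
#'
#' Tiles the 12x12 p-value-subset grid, filled by the proportion of
#' concordant SNPs and annotated with the Fisher odds ratio where tested.
#'
#' @param object A `seca_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot seca_result
#' @export
autoplot.seca_result <- function(object, ...) {
  cells <- as_tibble(object$cells)
  cells$p1 <- factor(cells$p1_cutoff, levels = seca_thresholds)
  cells$p2 <- factor(cells$p2_cutoff, levels = seca_thresholds)
  ggplot(cells, aes(x = .data$p1, y = .data$p2,
                    fill = .data$prop_concordant)) +
    geom_tile(colour = "grey85") +
    geom_text(aes(label = ifelse(is.na(.data$or_ft), "",
                                 sprintf("%.2f", .data$or_ft))),
              size = 2.4) +
    scale_fill_gradient2(midpoint = 0.5, low = "#2166ac", mid = "white",
                         high = "#b2182b", limits = c(0, 1),
                         name = "concordant") +
    labs(x = "dataset-1 p-value cutoff", y = "dataset-2 p-value cutoff",
         title = "SNP effect concordance grid (cell label: Fisher OR)") +
    theme_minimal()
}

#' Scatter plot of MR instruments with estimator slopes
#'
#' Plots outcome against exposure effects (oriented so exposure effects
#' are positive) with one fitted line per supplied estimator: slope from
#' the fit, intercept zero except for MR-Egger.
#'
#' @param data An `mr_data` tibble.
#' @param fits A list of `mr_fit` objects to overlay.
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(data, fits = list()) {
  flip <- sign(data$beta_exposure)
  d <- tibble(bx = abs(data$beta_exposure), by = data$beta_outcome * flip,
              sx = data$se_exposure, sy = data$se_outcome)
  lines <- bind_rows(lapply(fits, function(f) {
    tibble(method = f$method, slope = f$beta,
           intercept = if (!is.null(f$intercept)) f$intercept else 0)
  }))
  p <- ggplot(d, aes(x = .data$bx, y = .data$by)) +
    geom_errorbar(aes(ymin = .data$by - 1.96 * .data$sy,
                      ymax = .data$by + 1.96 * .data$sy),
                  width = 0, colour = "grey70") +
    geom_errorbarh(aes(xmin = .data$bx - 1.96 * .data$sx,
                       xmax = .data$bx + 1.96 * .data$sx),
                   height = 0, colour = "grey70") +
    geom_point() +
    labs(x = "SNP effect on exposure", y = "SNP effect on outcome") +
    theme_minimal()
  if (nrow(lines) > 0) {
    p <- p + geom_abline(data = lines,
                         aes(slope = .data$slope,
                             intercept = .data$intercept,
                             colour = .data$method))
  }
  p
}

#' Forest plot of leave-one-out MR refits
#'
#' @param loo Output of [mr_leave_one_out()].
#' @return A ggplot object.
#' @export
plot_mr_loo <- function(loo) {
  full <- loo$beta[loo$omitted == "none"]
  loo$omitted <- factor(loo$omitted,
                        levels = rev(loo$omitted))
  ggplot(loo, aes(x = .data$beta, y = .data$omitted)) +
    geom_vline(xintercept = full, linetype = "dashed", colour = "grey50") +
    geom_vline(xintercept = 0, colour = "grey80") +
    geom_errorbarh(aes(xmin = .data$beta - 1.96 * .data$se,
                       xmax = .data$beta + 1.96 * .data$se),
                   height = 0.2) +
    geom_point() +
    labs(x = "causal estimate (omitting the named SNP)", y = NULL) +
    theme_minimal()
}

#' Bar-style dot plot of enriched terms
#'
#' @param object An `enrichment_result`.
#' @param top Number of terms to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, top = 20, ...) {
  d <- head(as_tibble(object), top)
  d$term_name <- factor(d$term_name, levels = rev(unique(d$term_name)))
  ggplot(d, aes(x = -log10(.data$p_adj), y = .data$term_name,
                size = .data$k_overlap)) +
    geom_point() +
    geom_vline(xintercept = -log10(0.05), linetype = "dashed") +
    labs(x = expression(-log[10] ~ "adjusted p"), y = NULL,
         size = "overlap") +
    theme_minimal()
}
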