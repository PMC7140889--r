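# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

complement_alleles <- function(x) {
  chartr("ACGT", "TGCA", x)
}

is_palindromic <- function(a1, a2) {
  paste0(a1, a2) %in% c("AT", "TA", "CG", "GC")
}

two_sided_p <- function(z) {
  2 * stats::pnorm(-abs(z))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional (hypergeometric) exact test: the two-sided p-value sums the
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table. The odds ratio returned is the
#' sample odds ratio `(n11 * n22) / (n12 * n21)`, not the conditional MLE.
#'
#' @param n11,n12,n21,n22 Non-negative integer cell counts.
#' @return A list with elements `or` (sample odds ratio, `NA` when a margin is
#'   zero) and `p` (two-sided exact p-value; 1 when a margin is degenerate).
#' @examples
#' fisher_exact_2x2(5, 5, 5, 5)
#' @export
fisher_exact_2x2 <- function(n11, n12, n21, n22) {
  r1 <- n11 + n12
  r2 <- n21 + n22
  c1 <- n11 + n21
  total <- r1 + r2
  if (r1 == 0L || r2 == 0L || c1 == 0L || c1 == total) {
    return(list(or = NA_real_, p = 1))
  }
  or <- (n11 * n22) / (n12 * n21)
  if (n12 == 0 || n21 == 0) or <- Inf
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(n11, r1, r2, c1)
  # relative tolerance guards against ties lost to floating point
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(or = or, p = min(1, p))
}

clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lower <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower = lower, upper = upper)
}

# weighted least squares with delete-a-block jackknife standard errors.
# X: model matrix (no intercept column added here), y, w vectors,
# block: integer block label per row. Returns coefficients and jackknife ses.
wls_jackknife <- function(X, y, w, block) {
  X <- as.matrix(X)
  p <- ncol(X)
  Xw <- X * w
  A <- crossprod(Xw, X)
  b <- crossprod(Xw, y)
  est <- drop(solve(A, b))
  labs <- sort(unique(block))
  g <- length(labs)
  loo <- matrix(NA_real_, g, p)
  for (i in seq_along(labs)) {
    idx <- block == labs[i]
    Ai <- A - crossprod(Xw[idx, , drop = FALSE], X[idx, , drop = FALSE])
    bi <- b - crossprod(Xw[idx, , drop = FALSE], y[idx])
    loo[i, ] <- drop(solve(Ai, bi))
  }
  pseudo <- sweep(-loo * (g - 1), 2, g * est, "+")
  se <- sqrt(apply(pseudo, 2, stats::var) / g)
  list(est = est, se = se, n_blocks = g, loo = loo)
}

# contiguous jackknife block labels for m rows
jackknife_blocks <- function(m, n_blocks) {
  n_blocks <- max(2L, min(n_blocks, floor(m / 2)))
  sort(rep_len(seq_len(n_blocks), m))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (closed_lower) x >= lower else x > lower) &&
    (if (closed_upper) x <= upper else x < upper)
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number in %s%s, %s%s.",
                  name,
                  if (closed_lower) "[" else "(", format(lower),
                  format(upper), if (closed_upper) "]" else ")"))
  }
  invisible(x)
}
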