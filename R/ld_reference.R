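#' Block-diagonal LD reference
#'
#' An LD reference is an ordered list of blocks, each holding a vector of SNP
#' IDs and their correlation matrix `r` (unit diagonal). Correlation between
#' SNPs in different blocks is exactly zero by construction. This abstraction
#' stands in for a haplotype reference panel: clumping, LD scores, gene-based
#' tests and the synthetic-data generator all consume it.
#'
#' @param blocks A list; each element is a list with `snps` (character) and
#'   `r` (square numeric matrix with unit diagonal).
#' @param validate Check symmetry, bounds, unit diagonal and positive
#'   semi-definiteness of each block (default `TRUE`).
#' @return An object of class `ld_ref`.
#' @export
ld_reference <- function(blocks, validate = TRUE) {
  stopifnot(is.list(blocks))
  for (i in seq_along(blocks)) {
    bl <- blocks[[i]]
    if (!is.list(bl) || is.null(bl$snps) || is.null(bl$r)) {
      abort("Each LD block must be a list with elements `snps` and `r`.")
    }
    r <- as.matrix(bl$r)
    m <- length(bl$snps)
    if (!all(dim(r) == c(m, m))) {
      abort(sprintf("Block %d: matrix dimension does not match SNP count.", i))
    }
    if (validate) {
      if (max(abs(r - t(r))) > 1e-8) {
        abort(sprintf("Block %d: correlation matrix is not symmetric.", i))
      }
      if (any(abs(r) > 1 + 1e-8) || max(abs(diag(r) - 1)) > 1e-8) {
        abort(sprintf(
          "Block %d: entries must lie in [-1, 1] with unit diagonal.", i))
      }
      if (m > 1 && min(eigen(r, symmetric = TRUE,
                             only.values = TRUE)$values) < -1e-6) {
        abort(sprintf("Block %d: matrix is not positive semi-definite.", i))
      }
    }
    dimnames(r) <- list(bl$snps, bl$snps)
    blocks[[i]] <- list(snps = as.character(bl$snps), r = r)
  }
  snps <- unlist(lapply(blocks, `[[`, "snps"), use.names = FALSE)
  if (anyDuplicated(snps)) {
    abort("A SNP may appear in exactly one LD block.")
  }
  structure(
    list(blocks = blocks,
         index = tibble(
           snp_id = snps,
           block = rep(seq_along(blocks),
                       vapply(blocks, function(b) length(b$snps), 1L)),
           idx = unlist(lapply(blocks, function(b) seq_along(b$snps)),
                        use.names = FALSE))),
    class = "ld_ref")
}

#' Construct an LD reference of fully independent SNPs
#'
#' Every SNP becomes its own singleton block (pairwise r = 0), asserting
#' independence.
#'
#' @param snp_ids Character vector of SNP IDs.
#' @return An `ld_ref` object.
#' @export
ld_independent <- function(snp_ids) {
  snp_ids <- as.character(snp_ids)
  blocks <- lapply(snp_ids, function(s) {
    list(snps = s, r = matrix(1, 1, 1))
  })
  ld_reference(blocks, validate = FALSE)
}

#' @export
print.ld_ref <- function(x, ...) {
  sizes <- vapply(x$blocks, function(b) length(b$snps), 1L)
  cat(sprintf("<ld_ref> %d SNPs in %d block(s); block sizes %d-%d\n",
              sum(sizes), length(sizes), min(sizes), max(sizes)))
  invisible(x)
}

#' All SNP IDs in an LD reference
#' @param ld An `ld_ref` object.
#' @return Character vector of SNP IDs in block order.
#' @export
ld_snps <- function(ld) {
  ld$index$snp_id
}

# correlation submatrix for an arbitrary set of SNPs, block-diagonal across
# blocks; ids absent from the reference are treated as independent singletons
ld_submatrix <- function(ld, ids) {
  ids <- as.character(ids)
  r <- diag(1, length(ids))
  dimnames(r) <- list(ids, ids)
  hit <- match(ids, ld$index$snp_id)
  info <- ld$index[hit[!is.na(hit)], ]
  for (b in unique(info$block)) {
    sel <- info$snp_id[info$block == b]
    if (length(sel) > 1) {
      r[sel, sel] <- ld$blocks[[b]]$r[sel, sel]
    }
  }
  r
}

#' Write an LD reference to a directory
#'
#' One tab-separated file per block (`block_0001.tsv`, ...), with a `snp_id`
#' column followed by the dense correlation matrix, one named column per SNP.
#'
#' @param ld An `ld_ref` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_ld_reference <- function(ld, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(ld$blocks)) {
    bl <- ld$blocks[[i]]
    df <- as.data.frame(bl$r)
    names(df) <- bl$snps
    df <- cbind(snp_id = bl$snps, df)
    readr::write_tsv(df, file.path(dir, sprintf("block_%04d.tsv", i)),
                     progress = FALSE)
  }
  invisible(dir)
}

#' Read an LD reference from a directory
#'
#' @param dir Directory of per-block files written by [write_ld_reference()].
#' @return An `ld_ref` object.
#' @export
read_ld_reference <- function(dir) {
  files <- sort(list.files(dir, pattern = "^block_.*\\.tsv$",
                           full.names = TRUE))
  if (length(files) == 0) {
    abort(sprintf("No block files found in '%s'.", dir))
  }
  blocks <- lapply(files, function(f) {
    df <- readr::read_tsv(f, show_col_types = FALSE, progress = FALSE)
    snps <- as.character(df$snp_id)
    r <- as.matrix(df[, -1, drop = FALSE])
    list(snps = snps, r = r)
  })
  ld_reference(blocks)
}
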