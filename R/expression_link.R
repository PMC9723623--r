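# Expression-side analysis: median-of-ratios normalization, the NFR vs
# no-NFR expression contrast (Mann-Whitney), replicate QC correlation and
# row-z-score matrices for heatmap-style summaries.

# median-of-ratios size factors (genes with any zero count are excluded from
# the geometric-mean reference, as is standard)
size_factors <- function(counts) {
  stopifnot(ncol(counts) >= 2L)
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use)) stop("no gene with all-positive counts for size-factor estimation")
  apply(counts[use, , drop = FALSE], 2, function(cnt)
    exp(stats::median(log(cnt) - loggeo[use])))
}

#' Normalize a count matrix by median-of-ratios size factors
#'
#' @param raw non-negative gene x sample count matrix with >= 2 samples.
#' @return list of class `expression_matrix`: `counts` (raw), `normalized`
#'   (counts divided by size factors), `size_factors`.
#' @export
normalize_counts <- function(raw) {
  raw <- as.matrix(raw)
  if (any(raw < 0)) stop("negative counts")
  sf <- size_factors(raw)
  structure(list(counts = raw,
                 normalized = sweep(raw, 2, sf, "/"),
                 size_factors = sf),
            class = "expression_matrix")
}

#' Test for higher expression of NFR-containing genes
#'
#' One-sided Mann-Whitney U test that genes containing at least one
#' nucleosome-free region are more highly expressed than genes without one.
#' Expression is compared on the `log(normalized + 1)` scale.  The p-value is
#' exact (full enumeration) when both groups have <= 8 tie-free observations,
#' otherwise the normal approximation with continuity correction is used.
#'
#' @param expr numeric vector of per-gene expression values
#'   (log normalized counts).
#' @param gene_has_nfr logical vector, same length.
#' @return list `U` (statistic for the NFR group), `p_value` (one-sided,
#'   NFR > other), `median_nfr`, `median_other`, `exact`.
#' @export
nfr_expression_test <- function(expr, gene_has_nfr) {
  stopifnot(length(expr) == length(gene_has_nfr))
  x <- expr[gene_has_nfr]   # NFR group
  y <- expr[!gene_has_nfr]
  if (length(x) == 0L || length(y) == 0L) stop("empty group")
  exact <- length(x) <= 8L && length(y) <= 8L &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                                            exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       median_nfr = stats::median(x), median_other = stats::median(y),
       exact = exact)
}

#' Replicate Spearman correlation with QC warning
#'
#' @param x,y equal-length numeric vectors, n >= 3, non-constant.
#' @param warn_below warn when rho falls below this QC tier (default 0.8).
#' @return Spearman rho (average ranks for ties).
#' @export
replicate_correlation <- function(x, y, warn_below = 0.8) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: rank correlation undefined")
  rho <- stats::cor(x, y, method = "spearman")
  if (rho < warn_below)
    warning(sprintf("replicate correlation rho = %.3f below QC tier %.2f",
                    rho, warn_below))
  rho
}

#' Row z-scores of log expression for a gene subset
#'
#' Per row: `z = (log(x + 1) - row mean) / row sd`.  Constant rows become
#' all-zero with a warning.
#'
#' @param expr non-negative gene x sample matrix (normalized counts).
#' @param genes character vector of row names to extract (default all).
#' @return numeric matrix of z-scores, same columns as `expr`.
#' @export
row_zscore_log <- function(expr, genes = rownames(expr)) {
  stopifnot(ncol(expr) >= 2L)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) stop("genes not in matrix: ", paste(missing, collapse = ", "))
  lg <- log(expr[genes, , drop = FALSE] + 1)
  m <- rowMeans(lg)
  s <- apply(lg, 1, stats::sd)
  const <- s == 0
  if (any(const)) {
    warning(sum(const), " constant rows set to zero")
    s[const] <- 1
  }
  z <- (lg - m) / s
  z[const, ] <- 0
  z
}
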