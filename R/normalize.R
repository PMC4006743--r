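#' Median-of-ratios size factors
#'
#' For every gene with strictly positive counts in all samples, the ratio of
#' its count in a sample to its geometric mean across samples is formed; the
#' sample's size factor is the median of these ratios. This assumes most
#' genes are not differentially expressed, so the median ratio tracks
#' sequencing depth rather than biology. Genes with a zero in any sample are
#' excluded from the estimation (their geometric mean is zero) but are still
#' normalized and filterable downstream.
#'
#' @param counts Gene x sample numeric matrix of raw counts.
#' @return Named positive numeric vector of per-sample size factors.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), 3,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' compute_size_factors(m)  # c(1/sqrt(2), sqrt(2))
#' @export
compute_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  eligible <- rowSums(counts > 0) == ncol(counts)
  if (!any(eligible)) {
    stop("degenerate input: no gene has positive counts in every sample")
  }
  pos <- counts[eligible, , drop = FALSE]
  geomean <- exp(rowMeans(log(pos)))
  ratios <- pos / geomean
  factors <- apply(ratios, 2L, stats::median)
  stats::setNames(factors, colnames(counts))
}

#' Normalize counts by size factors
#'
#' Divides each sample's column by its size factor and flags the matrix as
#' normalized (`attr(, "normalized")`).
#'
#' @param counts Gene x sample numeric matrix.
#' @param factors Named size factors covering every sample.
#' @return Normalized matrix of the same dimension.
#' @export
normalize_counts <- function(counts, factors) {
  counts <- as.matrix(counts)
  missing <- setdiff(colnames(counts), names(factors))
  if (is.null(colnames(counts)) && length(factors) != ncol(counts)) {
    stop("size factors do not cover all samples")
  }
  if (length(missing)) {
    stop("missing size factor for sample(s): ",
         paste(missing, collapse = ", "))
  }
  f <- if (is.null(colnames(counts))) factors else factors[colnames(counts)]
  if (any(f <= 0)) stop("size factors must be positive")
  out <- sweep(counts, 2L, f, `/`)
  attr(out, "normalized") <- TRUE
  out
}

#' Remove the lowest-expressed fraction of genes
#'
#' Ranks genes by their total normalized count across all samples and removes
#' the `ceiling(quantile * G)` smallest, the convention under which a
#' 5792-gene genome retains exactly 4633 genes at the default 20%. Ties in
#' totals are broken by gene label order, for determinism. Intended to reduce
#' the number of tested hypotheses before per-gene modeling.
#'
#' @param counts Normalized gene x sample matrix (see [normalize_counts()]).
#' @param quantile Fraction of genes to remove, in \[0, 1).
#' @return The surviving rows, original order preserved; removed gene ids in
#'   `attr(, "removed")`.
#' @export
filter_low_expression <- function(counts, quantile = 0.20) {
  counts <- as.matrix(counts)
  if (!isTRUE(attr(counts, "normalized"))) {
    stop("counts must be normalized before filtering (see normalize_counts)")
  }
  if (quantile < 0 || quantile >= 1) stop("'quantile' must be in [0, 1)")
  G <- nrow(counts)
  k <- ceiling(quantile * G)
  if (k >= G) stop("degenerate input: filter would remove all genes")
  if (k == 0L) return(counts)
  totals <- rowSums(counts)
  labels <- rownames(counts)
  if (is.null(labels)) labels <- sprintf("row%06d", seq_len(G))
  drop_idx <- order(totals, labels)[seq_len(k)]
  out <- counts[-drop_idx, , drop = FALSE]
  attr(out, "normalized") <- TRUE
  attr(out, "removed") <- labels[sort(drop_idx)]
  out
}
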