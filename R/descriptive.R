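#' Day-correct counts on the original expression scale
#'
#' Divides each gene's normalized counts by the ratio of the gene's mean
#' expression on the sample's day to its mean on a chosen reference day,
#' equalizing per-gene day means while staying on the count scale (the
#' multiplicative counterpart of day residualization, appropriate for
#' scale-dependent summaries such as the CV). Reference-day samples are
#' unchanged. Genes whose mean on any day is zero cannot be corrected; they
#' are left as-is and listed in `attr(, "uncorrected")`.
#'
#' @param counts Normalized gene x sample matrix.
#' @param sample_table Sample table aligned to `colnames(counts)`.
#' @param reference_day Day label used as the anchor (arbitrary choice).
#' @return Corrected matrix of the same dimension.
#' @export
day_correct_counts <- function(counts, sample_table, reference_day) {
  validate_sample_table(sample_table)
  counts <- as.matrix(counts)
  ord <- match(colnames(counts), sample_table$sample_id)
  if (anyNA(ord)) stop("count columns without sample-table entries")
  day <- as.character(sample_table$day[ord])
  days <- unique(day)
  if (!reference_day %in% days) {
    stop("reference day '", reference_day, "' has no samples")
  }
  day_means <- sapply(days, function(d) {
    rowMeans(counts[, day == d, drop = FALSE])
  })
  day_means <- matrix(day_means, nrow = nrow(counts),
                      dimnames = list(rownames(counts), days))
  uncorrectable <- rowSums(day_means == 0) > 0
  ratio <- day_means / day_means[, reference_day]
  out <- counts
  ok <- !uncorrectable
  out[ok, ] <- counts[ok, , drop = FALSE] /
    ratio[ok, day, drop = FALSE]
  attr(out, "normalized") <- attr(counts, "normalized")
  attr(out, "uncorrected") <- rownames(counts)[uncorrectable]
  out
}

#' Coefficient of variation of a replicate vector
#'
#' Sample standard deviation (n-1 denominator) over the mean — the
#' scale-free replicate-noise measure used to compare measurement noise
#' across expression and phenotype. Undefined when the mean is zero.
#'
#' @param values Numeric vector of >= 2 replicate measurements.
#' @return One-row data frame: `sigma`, `mu`, `cv`, `undefined`.
#' @examples
#' coefficient_of_variation(c(1, 2, 3))  # sd 1, mean 2, cv 0.5
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("need >= 2 replicate values")
  sigma <- stats::sd(values)
  mu <- mean(values)
  undefined <- mu == 0
  data.frame(sigma = sigma, mu = mu,
             cv = if (undefined) NA_real_ else sigma / mu,
             undefined = undefined)
}

#' Per-gene, per-strain replicate CV of expression
#'
#' Computes the CV across biological replicates of each strain for every
#' gene, typically on day-corrected normalized counts (see
#' [day_correct_counts()]) so day-to-day shifts do not inflate the
#' replicate noise estimate.
#'
#' @param counts Gene x sample matrix.
#' @param sample_table Sample table aligned to `colnames(counts)`.
#' @return Data frame with `gene_id`, `strain_id`, `sigma`, `mu`, `cv`,
#'   `undefined`; strains with fewer than 2 samples are skipped.
#' @export
expression_cv <- function(counts, sample_table) {
  validate_sample_table(sample_table)
  counts <- as.matrix(counts)
  ord <- match(colnames(counts), sample_table$sample_id)
  if (anyNA(ord)) stop("count columns without sample-table entries")
  strain <- sample_table$strain_id[ord]
  strains <- unique(strain)
  strains <- strains[vapply(strains, function(s) sum(strain == s) >= 2L,
                            logical(1))]
  out <- do.call(rbind, lapply(strains, function(s) {
    sub <- counts[, strain == s, drop = FALSE]
    mu <- rowMeans(sub)
    sigma <- apply(sub, 1L, stats::sd)
    data.frame(gene_id = rownames(counts), strain_id = s, sigma = sigma,
               mu = mu, cv = ifelse(mu == 0, NA_real_, sigma / mu),
               undefined = mu == 0, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-strain replicate CV of a phenotype
#'
#' @param phenotypes Data frame with `strain_id`, `replicate`, `efficiency`.
#' @return Data frame with `strain_id`, `sigma`, `mu`, `cv`, `undefined`.
#' @export
phenotype_cv <- function(phenotypes) {
  strains <- unique(phenotypes$strain_id)
  out <- do.call(rbind, lapply(strains, function(s) {
    cbind(strain_id = s,
          coefficient_of_variation(
            phenotypes$efficiency[phenotypes$strain_id == s]))
  }))
  rownames(out) <- NULL
  out
}

#' Compare two alleles' per-gene variance-share profiles
#'
#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test with the normal
#' approximation, tie correction and continuity correction, two-sided. Used
#' to ask whether the rank order of the amount of variance explained differs
#' between two alleles over the same gene set.
#'
#' @param shares_a,shares_b Numeric vectors of per-gene variance fractions
#'   for the two alleles (need not be equal length for the test itself).
#' @return List with `statistic` (the Mann-Whitney U for the first sample),
#'   `p_value` (two-sided; 1 when all values are tied), and `method`.
#' @export
compare_allele_rankings <- function(shares_a, shares_b) {
  x <- as.numeric(shares_a)
  y <- as.numeric(shares_b)
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty")
  all_r <- rank(c(x, y))
  u <- sum(all_r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nt <- n1 + n2
  ties <- table(c(x, y))
  sigma2 <- (n1 * n2 / 12) *
    ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
  if (sigma2 <= 0) {
    return(list(statistic = u, p_value = 1,
                method = "Wilcoxon rank-sum, normal approximation"))
  }
  z <- u - mu
  z <- z - sign(z) * 0.5                      # continuity correction
  z <- z / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = u, p_value = p,
       method = "Wilcoxon rank-sum, normal approximation with tie correction")
}
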