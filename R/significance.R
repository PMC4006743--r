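#' Benjamini-Hochberg FDR control of per-gene model p-values
#'
#' Step-up BH adjustment; genes with adjusted p at or below `fdr` are called
#' significant. The largest unadjusted p-value among the rejections (the
#' genome-wide unadjusted threshold implied by the FDR cut) is attached as
#' `attr(, "max_significant_p")`.
#'
#' @param p_values Numeric vector of model p-values in \[0, 1\]; names are
#'   taken as gene ids.
#' @param fdr Target false discovery rate (default 0.10).
#' @return Data frame with `gene_id`, `model_p`, `adjusted_p`,
#'   `significant`; attributes `fdr` and `max_significant_p` (`NA` if no
#'   rejections).
#' @export
bh_adjust <- function(p_values, fdr = 0.10) {
  if (length(p_values) == 0L) {
    out <- data.frame(gene_id = character(0), model_p = numeric(0),
                      adjusted_p = numeric(0), significant = logical(0))
    attr(out, "fdr") <- fdr
    attr(out, "max_significant_p") <- NA_real_
    return(out)
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  ids <- names(p_values)
  if (is.null(ids)) ids <- sprintf("gene_%04d", seq_along(p_values))
  adj <- stats::p.adjust(p_values, method = "BH")
  sig <- !is.na(adj) & adj <= fdr
  out <- data.frame(gene_id = ids, model_p = as.numeric(p_values),
                    adjusted_p = as.numeric(adj), significant = sig,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "fdr") <- fdr
  attr(out, "max_significant_p") <-
    if (any(sig)) max(out$model_p[sig]) else NA_real_
  out
}

#' Genotype-permutation null for the genome-wide model p-value threshold
#'
#' Permutes the strain-to-sample assignment — each sample's four-locus
#' genotype vector is kept intact and reassigned as a block, preserving
#' the multiset of genotype vectors — refits the full factorial model to
#' every gene of the (already day-residualized) expression matrix, and
#' records a low percentile (default the 5th) of the genome-wide model
#' p-value distribution. Repeating this builds the null distribution of
#' that percentile, against which the observed percentile (also returned)
#' can be compared; an observed value well below `mean - 2 sd` of the null
#' indicates genuine genotype signal.
#'
#' Day residualization is done once, before permutation: the day is a
#' property of the sample, not of the genotype being permuted. Each
#' permutation replicate uses its own RNG stream derived from the master
#' seed, so replicates are order-insensitive.
#'
#' @param residuals Gene x sample matrix of day-residual expression.
#' @param sample_table Sample table aligned to `colnames(residuals)`.
#' @param panel A `genotype_panel`.
#' @param n_perm Number of permutation replicates (>= 1; default 1000).
#' @param percentile Probability level of the recorded percentile
#'   (default 0.05).
#' @param seed Master RNG seed.
#' @param stratify_by_day If `TRUE`, permute sample labels only within day
#'   strata (off by default).
#' @return A `permutation_null` data frame with `replicate` and
#'   `percentile_p`; attributes `observed` (the unpermuted percentile),
#'   `mean`, `sd`, `percentile`, `n_perm`.
#' @export
permutation_threshold <- function(residuals, sample_table, panel,
                                  n_perm = 1000L, percentile = 0.05,
                                  seed = 1L, stratify_by_day = FALSE) {
  if (n_perm < 1L) stop("'n_perm' must be >= 1")
  validate_sample_table(sample_table, panel)
  Y <- as.matrix(residuals)
  ord <- match(colnames(Y), sample_table$sample_id)
  if (anyNA(ord)) stop("residual columns without sample-table entries")
  sample_table <- sample_table[ord, , drop = FALSE]
  strains <- sample_table$strain_id
  n <- length(strains)
  genotypes <- unique(strains)
  if (length(genotypes) < 2L) {
    stop("need >= 2 distinct genotype vectors among the samples")
  }
  day <- sample_table$day
  df_adjust <- attr(residuals, "df_consumed")
  if (is.null(df_adjust)) df_adjust <- 0L
  observed <- perm_percentile(Y, strains, panel, sample_table, percentile,
                              df_adjust)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_perm)
  percentile_p <- vapply(seq_len(n_perm), function(i) {
    set.seed(rep_seeds[i])
    perm <- if (stratify_by_day) {
      idx <- seq_len(n)
      for (d in unique(day)) {
        w <- which(day == d)
        idx[w] <- w[sample.int(length(w))]
      }
      idx
    } else {
      sample.int(n)
    }
    shuffled <- strains[perm]
    stopifnot(identical(sort(shuffled), sort(strains)))  # multiset preserved
    perm_percentile(Y, shuffled, panel, sample_table, percentile,
                    df_adjust)
  }, numeric(1))
  out <- data.frame(replicate = seq_len(n_perm), percentile_p = percentile_p)
  class(out) <- c("permutation_null", "data.frame")
  attr(out, "observed") <- observed
  attr(out, "mean") <- mean(percentile_p)
  attr(out, "sd") <- stats::sd(percentile_p)
  attr(out, "percentile") <- percentile
  attr(out, "n_perm") <- n_perm
  out
}

perm_percentile <- function(Y, strains, panel, sample_table, percentile,
                            df_adjust = 0L) {
  st <- sample_table
  st$strain_id <- strains
  X <- build_design_matrix(panel, st)
  p <- genomewide_model_p(Y, X, df_adjust = df_adjust)
  as.numeric(stats::quantile(p, probs = percentile, names = FALSE))
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "Permutation null of the %.0fth-percentile model p (%d replicates)\n",
    100 * attr(x, "percentile"), attr(x, "n_perm")))
  cat(sprintf("  null mean %.4g, sd %.4g; observed %.4g (%.2f sd below mean)\n",
              attr(x, "mean"), attr(x, "sd"), attr(x, "observed"),
              (attr(x, "mean") - attr(x, "observed")) / attr(x, "sd")))
  invisible(x)
}
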