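#' Ground-truth effect structure for phenotype simulation
#'
#' Bundles the true model underlying simulated sporulation efficiencies:
#' an intercept (the all-oak strain mean, in percent), named effects `beta`
#' for any subset of the factorial terms (vineyard-allele coding: a term's
#' effect is added when all its loci carry the V allele), and a gaussian
#' replicate noise standard deviation.
#'
#' @param intercept All-oak strain mean efficiency (percent).
#' @param beta Named numeric vector of term effects; names must be factorial
#'   term labels (e.g. `"RME1nc"`, `"RSF1c:IME1c"`). May be empty.
#' @param noise_sd Replicate noise standard deviation (>= 0).
#' @return A `phenotype_truth` list.
#' @export
phenotype_truth <- function(intercept = 50, beta = numeric(0), noise_sd = 0) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (length(beta) && is.null(names(beta))) {
    stop("'beta' must be a named vector of factorial term effects")
  }
  structure(list(intercept = intercept, beta = beta, noise_sd = noise_sd),
            class = "phenotype_truth")
}

#' Solve main-effect sizes from target variance fractions
#'
#' For a balanced full factorial panel with main effects only, converts
#' target per-locus fractions of total phenotypic variance into effect sizes.
#' With `N` observations, V-allele indicator coding, and replicate noise
#' `noise_sd`, the expected sequential sum of squares of a main effect `b` is
#' `N b^2 / 4 + sigma^2`, every null term contributes `sigma^2` in
#' expectation and the residual `(N - 2^L) sigma^2`, which yields a closed
#' form for the `b` that attains each target fraction in expectation.
#'
#' The default intercept and noise are chosen so every cell mean of the
#' resulting truth lies well inside \[0, 100\] and the percentage clipping
#' applied by [simulate_phenotypes()] is negligible.
#'
#' @param fractions Named vector of target main-effect variance fractions in
#'   percent (names = loci). Their sum must be < 100.
#' @param reps Replicates per strain (design is `2^L * reps` observations).
#' @param noise_sd Replicate noise standard deviation (percent).
#' @param intercept All-oak strain mean (percent).
#' @param sign Direction of the vineyard effects (default `-1`: vineyard
#'   alleles lower sporulation efficiency).
#' @return A `phenotype_truth` whose fitted factorial ANOVA recovers the
#'   target fractions in expectation.
#' @examples
#' tr <- phenotype_truth_from_fractions(
#'   c(RME1nc = 34, RSF1c = 20, IME1c = 32, IME1nc = 6.5))
#' @export
phenotype_truth_from_fractions <- function(fractions,
                                           reps = 4L,
                                           noise_sd = 4,
                                           intercept = 90,
                                           sign = -1) {
  loci <- names(fractions)
  if (is.null(loci)) stop("'fractions' must be named by locus")
  f <- fractions / 100
  L <- length(loci)
  N <- 2^L * reps
  p_terms <- 2^L - 1L                 # non-intercept terms in the full model
  n_true <- L
  if (sum(f) >= 1) stop("target fractions must sum to < 100%")
  sigma2 <- noise_sd^2
  # E[SS_total] = sum(N b^2 / 4) + (N - 1) sigma^2 and
  # f_t * E[SS_total] = N b_t^2 / 4 + sigma^2  =>
  total <- (N - 1 - n_true) * sigma2 / (1 - sum(f))
  b2 <- (f * total - sigma2) * 4 / N
  if (any(b2 < 0)) {
    stop("target fractions too small relative to noise; increase fractions ",
         "or reduce 'noise_sd'")
  }
  beta <- sign * sqrt(b2)
  names(beta) <- loci
  phenotype_truth(intercept = intercept, beta = beta, noise_sd = noise_sd)
}

#' Simulate per-replicate sporulation efficiencies
#'
#' Each observation is `intercept + sum(beta_t x_t) + N(0, noise_sd)`,
#' clipped to \[0, 100\] (efficiencies are percentages), where `x_t` is the
#' product of vineyard-allele indicators for term `t`. Reproducible given a
#' seed.
#'
#' @param panel A `genotype_panel`.
#' @param truth A `phenotype_truth`.
#' @param reps Replicates per strain (>= 1).
#' @param seed Integer RNG seed.
#' @return A phenotype table: data frame with `strain_id`, `replicate`,
#'   `efficiency`.
#' @export
simulate_phenotypes <- function(panel, truth, reps = 4L, seed = 1L) {
  validate_panel(panel)
  stopifnot(inherits(truth, "phenotype_truth"), reps >= 1L)
  X <- build_design_matrix(panel)
  mu <- rep(truth$intercept, nrow(X))
  if (length(truth$beta)) {
    unknown <- setdiff(names(truth$beta), colnames(X))
    if (length(unknown)) {
      stop("truth has effects for unknown term(s): ",
           paste(unknown, collapse = ", "))
    }
    mu <- mu + drop(X[, names(truth$beta), drop = FALSE] %*% truth$beta)
  }
  set.seed(seed)
  out <- expand.grid(replicate = seq_len(reps), strain_id = panel$strain_id,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("strain_id", "replicate")]
  means <- mu[match(out$strain_id, panel$strain_id)]
  eff <- means + stats::rnorm(nrow(out), sd = truth$noise_sd)
  out$efficiency <- pmin(100, pmax(0, eff))
  rownames(out) <- NULL
  out
}

#' Ground-truth effect structure for expression simulation
#'
#' Random (or user-specified) per-gene truth for the count simulator. Two
#' modes mirror the two batch-correction styles the analysis supports:
#' `"gaussian"` (additive day offsets on the count scale, gaussian noise,
#' counts rounded and floored at zero) and `"nb"` (negative binomial with
#' multiplicative day factors on the mean; effects act on the log scale).
#'
#' A fraction `prop_affected` of genes receives nonzero genotype effects;
#' affected genes get main effects and (with `interaction_effect_sd > 0`)
#' two-way interaction effects drawn from centered gaussians. All sampling is
#' controlled by `seed`, independent of the count-level seed used later.
#'
#' @param n_genes Number of genes.
#' @param loci Locus labels (default the four QTN).
#' @param days Day labels of the batches.
#' @param mode `"gaussian"` or `"nb"`.
#' @param prop_affected Fraction of genes with genotype effects.
#' @param main_effect_sd,interaction_effect_sd SDs of the effect draws
#'   (count scale in gaussian mode, log scale in NB mode).
#' @param base_mean Mean of per-gene baseline (count scale, gaussian mode).
#' @param base_log_mean,base_log_sd Baseline `log` expression (NB mode).
#' @param day_effect_sd Spread of day effects: additive offsets
#'   `N(0, day_effect_sd)` in gaussian mode; log-multipliers
#'   `exp(N(0, day_effect_sd))` in NB mode (so multipliers are strictly
#'   positive, first day anchored at 1).
#' @param noise_sd Gaussian replicate noise SD (gaussian mode).
#' @param dispersion NB size parameter (variance = mu + mu^2/size; NB mode).
#' @param seed Integer seed for the truth draws.
#' @return An `expression_truth` list with elements `mode`, `gene_id`,
#'   `intercept`, `beta` (genes x terms matrix), `day_offset` or
#'   `day_multiplier`, `noise_sd` or `dispersion`, and `affected` (logical).
#' @export
expression_truth <- function(n_genes,
                             loci = qtn_loci(),
                             days = LETTERS[1:4],
                             mode = c("gaussian", "nb"),
                             prop_affected = 0.05,
                             main_effect_sd = if (mode == "nb") 0.5 else 60,
                             interaction_effect_sd = main_effect_sd / 2,
                             base_mean = 300,
                             base_log_mean = 5.5,
                             base_log_sd = 1.2,
                             day_effect_sd = if (mode == "nb") 0.15 else 30,
                             noise_sd = 40,
                             dispersion = 10,
                             seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_genes >= 1L)
  set.seed(seed)
  terms <- factorial_terms(loci)
  gene_id <- sprintf("gene_%04d", seq_len(n_genes))
  beta <- matrix(0, n_genes, length(terms), dimnames = list(gene_id, terms))
  affected <- stats::runif(n_genes) < prop_affected
  two_way <- terms[lengths(strsplit(terms, ":", fixed = TRUE)) == 2L]
  n_aff <- sum(affected)
  if (n_aff > 0L) {
    beta[affected, loci] <- stats::rnorm(n_aff * length(loci),
                                         sd = main_effect_sd)
    if (interaction_effect_sd > 0) {
      beta[affected, two_way] <- stats::rnorm(n_aff * length(two_way),
                                              sd = interaction_effect_sd)
    }
  }
  tr <- list(mode = mode, gene_id = gene_id, beta = beta, affected = affected)
  if (mode == "gaussian") {
    tr$intercept <- stats::rnorm(n_genes, mean = base_mean,
                                 sd = base_mean / 4)
    tr$day_offset <- stats::setNames(
      c(0, stats::rnorm(length(days) - 1L, sd = day_effect_sd))[
        seq_along(days)], days)
    tr$noise_sd <- noise_sd
  } else {
    tr$intercept <- stats::rnorm(n_genes, mean = base_log_mean,
                                 sd = base_log_sd)
    tr$day_multiplier <- stats::setNames(
      exp(c(0, stats::rnorm(length(days) - 1L, sd = day_effect_sd))[
        seq_along(days)]), days)
    tr$dispersion <- dispersion
  }
  structure(tr, class = "expression_truth")
}

#' Simulate an overdispersed expression count matrix
#'
#' Draws a gene x sample count matrix from a known truth over a genotype
#' panel and sample layout. In gaussian mode,
#' `count = max(0, round(intercept + X beta + day_offset + N(0, noise_sd)))`;
#' in NB mode, `count ~ NegBin(mean = day_multiplier * exp(intercept +
#' X beta), size = dispersion)`. The truth is returned alongside the counts
#' so recovery can be tested.
#'
#' @param panel A `genotype_panel`.
#' @param sample_table Sample table (see [make_sample_table()]); every day
#'   label must have a day effect in the truth.
#' @param truth An `expression_truth`.
#' @param seed Integer RNG seed for the count draws.
#' @return List with `counts` (gene x sample integer matrix, dimnames set)
#'   and `truth`.
#' @export
simulate_expression_counts <- function(panel, sample_table, truth,
                                       seed = 1L) {
  validate_panel(panel)
  validate_sample_table(sample_table, panel)
  stopifnot(inherits(truth, "expression_truth"))
  day_effects <- if (truth$mode == "gaussian") truth$day_offset else
    truth$day_multiplier
  unknown <- setdiff(unique(sample_table$day), names(day_effects))
  if (length(unknown)) {
    stop("sample day(s) without a truth day effect: ",
         paste(unknown, collapse = ", "))
  }
  X <- build_design_matrix(panel, sample_table)
  G <- length(truth$gene_id)
  S <- nrow(sample_table)
  signal <- truth$intercept +
    truth$beta %*% t(X[, colnames(truth$beta), drop = FALSE])
  set.seed(seed)
  if (truth$mode == "gaussian") {
    mu <- sweep(signal, 2L, truth$day_offset[sample_table$day], `+`)
    counts <- matrix(pmax(0, round(mu + stats::rnorm(G * S,
                                                     sd = truth$noise_sd))),
                     G, S)
  } else {
    mu <- sweep(exp(signal), 2L, truth$day_multiplier[sample_table$day], `*`)
    counts <- matrix(stats::rnbinom(G * S, mu = as.vector(mu),
                                    size = truth$dispersion), G, S)
  }
  dimnames(counts) <- list(truth$gene_id, sample_table$sample_id)
  list(counts = counts, truth = truth)
}
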