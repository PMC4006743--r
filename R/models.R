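#' Factorial model term labels for a set of loci
#'
#' Non-intercept terms of the full factorial model, ordered by interaction
#' order and, within an order, by the combination order of the loci: the four
#' main effects, the six two-way, four three-way and one four-way interaction
#' for the default panel. Interaction labels join loci with `":"`.
#'
#' @param loci Character vector of locus labels.
#' @return Character vector of `2^L - 1` term labels.
#' @export
factorial_terms <- function(loci = qtn_loci()) {
  unlist(lapply(seq_along(loci), function(k) {
    apply(utils::combn(loci, k), 2L, paste, collapse = ":")
  }), use.names = FALSE)
}

#' Build the full factorial design matrix
#'
#' Treatment (dummy) coding with the oak allele as the reference level: each
#' main-effect column is the vineyard-allele indicator (V = 1, O = 0) and
#' each interaction column is the elementwise product of its constituent main
#' columns. The intercept therefore estimates the mean of the all-oak strain
#' and every other coefficient the effect of swapping in vineyard alleles.
#' Column order: intercept, main effects in locus order, then interactions of
#' increasing order.
#'
#' @param panel A `genotype_panel`.
#' @param sample_table Optional sample table; if given, the matrix has one
#'   row per sample (strains looked up from the panel), otherwise one row per
#'   strain.
#' @return Numeric 0/1 matrix with row names (sample or strain ids), column
#'   names the term labels, and attributes `loci` and `strain_id` (the strain
#'   behind each row).
#' @examples
#' panel <- make_full_factorial_panel()
#' X <- build_design_matrix(panel)
#' dim(X)       # 16 x 16
#' qr(X)$rank   # 16
#' @export
build_design_matrix <- function(panel, sample_table = NULL) {
  validate_panel(panel)
  loci <- panel_loci(panel)
  if (is.null(sample_table)) {
    strains <- panel$strain_id
    row_ids <- strains
  } else {
    validate_sample_table(sample_table, panel)
    strains <- sample_table$strain_id
    row_ids <- sample_table$sample_id
  }
  idx <- match(strains, panel$strain_id)
  main <- sapply(loci, function(l) as.numeric(panel[[l]][idx] == "V"))
  main <- matrix(main, nrow = length(idx), dimnames = list(NULL, loci))
  terms <- factorial_terms(loci)
  X <- matrix(1, nrow = length(idx), ncol = length(terms) + 1L,
              dimnames = list(row_ids, c("(Intercept)", terms)))
  for (term in terms) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1L]]
    X[, term] <- apply(main[, parts, drop = FALSE], 1L, prod)
  }
  attr(X, "loci") <- loci
  attr(X, "strain_id") <- strains
  X
}

#' Remove day-of-growth batch effects by per-gene residualization
#'
#' Fits, gene by gene, an ordinary least-squares model of the normalized
#' counts on the day of growth (a categorical batch factor, with intercept)
#' and returns the residuals. This is the first stage of the two-stage
#' analysis: day is a property of the sample, not the genotype, so its
#' additive effect is removed before any genotype modeling.
#'
#' @param counts Gene x sample numeric matrix (normalized counts).
#' @param sample_table Sample table whose `sample_id` matches `colnames(counts)`.
#' @return Residual matrix of the same dimension; per gene, residuals sum to
#'   zero within each day level (up to numerical tolerance). The number of
#'   degrees of freedom the day model consumed beyond the grand mean
#'   (`n_days - 1`) is attached as `attr(, "df_consumed")` so downstream
#'   model F-tests can account for it.
#' @export
fit_day_residuals <- function(counts, sample_table) {
  validate_sample_table(sample_table)
  counts <- as.matrix(counts)
  ord <- match(colnames(counts), sample_table$sample_id)
  if (anyNA(ord)) {
    stop("count columns without sample-table entries: ",
         paste(colnames(counts)[is.na(ord)], collapse = ", "))
  }
  day <- factor(sample_table$day[ord])
  if (any(table(day) == 0L)) stop("day level with no samples")
  D <- if (nlevels(day) > 1L) stats::model.matrix(~day) else
    matrix(1, length(day), 1L)
  # residual projection applied to all genes at once
  Yt <- t(counts)                                   # samples x genes
  fit <- stats::lm.fit(D, Yt)
  res <- t(fit$residuals)
  dimnames(res) <- dimnames(counts)
  attr(res, "df_consumed") <- nlevels(day) - 1L
  res
}

#' Fit the full factorial genotype model to one response
#'
#' Ordinary least squares of a response (one gene's day-residual expression,
#' or a phenotype vector) on the full factorial design: all main and
#' interaction effects of the vineyard alleles. Reports coefficients, the
#' overall F test of all non-intercept terms, and R-squared. With
#' `response_transform = "log"` the response is `log(y + 1)` and the day
#' indicators enter the same model as covariates (the one-stage alternative
#' to prior day residualization).
#'
#' @param response Numeric response vector, one value per design row.
#' @param design Design matrix from [build_design_matrix()].
#' @param response_transform `"identity"` or `"log"` (`log(y + 1)`; requires
#'   a nonnegative response).
#' @param day Factor/character of day labels per observation; required for
#'   the log variant, ignored otherwise.
#' @param df_adjust Degrees of freedom already consumed upstream of this fit
#'   (e.g. `attr(residuals, "df_consumed")` from [fit_day_residuals()]);
#'   subtracted from the residual df so two-stage F-tests stay calibrated.
#' @param gene_id Label carried into the result (default `"response"`).
#' @return A `model_fit` list: `gene_id`, `coefficients` (NA for aliased
#'   terms), `r_squared`, `model_f`, `model_p`, `df_model`, `df_residual`,
#'   `residual_ss`, `total_ss`, plus `response`, `design`, `residuals` for
#'   downstream decomposition. A zero-variance response is reported with
#'   `r_squared = 0` and `model_p = 1`.
#' @export
fit_genotype_model <- function(response, design,
                               response_transform = c("identity", "log"),
                               day = NULL, df_adjust = 0L,
                               gene_id = "response") {
  response_transform <- match.arg(response_transform)
  y <- as.numeric(response)
  X <- as.matrix(design)
  if (length(y) != nrow(X)) stop("response length does not match design rows")
  if (response_transform == "log") {
    if (any(y < 0)) stop("log transform requires a nonnegative response")
    y <- log(y + 1)
    if (is.null(day)) stop("the log-model variant requires 'day' covariates")
    day <- factor(day)
    if (nlevels(day) > 1L) {
      Dday <- stats::model.matrix(~day)[, -1L, drop = FALSE]
      colnames(Dday) <- paste0("DAY", levels(day)[-1L])
      X <- cbind(X, Dday)
    }
  }
  n <- length(y)
  fit <- stats::lm.fit(X, y)
  rank <- fit$rank
  if (n <= rank + df_adjust) {
    stop("too few observations for the model (n <= rank)")
  }
  aliased <- is.na(fit$coefficients)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  df_model <- rank - 1L
  df_residual <- n - rank - as.integer(df_adjust)
  if (tss <= .Machine$double.eps * max(1, mean(y)^2) * n) {
    r2 <- 0; f <- 0; p <- 1; rss <- 0; tss <- 0
  } else {
    r2 <- 1 - rss / tss
    f <- ((tss - rss) / df_model) / (rss / df_residual)
    p <- stats::pf(f, df_model, df_residual, lower.tail = FALSE)
  }
  structure(list(
    gene_id = gene_id,
    coefficients = fit$coefficients,
    aliased = names(fit$coefficients)[aliased],
    r_squared = r2,
    model_f = f,
    model_p = p,
    df_model = df_model,
    df_residual = df_residual,
    residual_ss = rss,
    total_ss = tss,
    response = y,
    design = X,
    residuals = fit$residuals
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Factorial model fit for %s\n", x$gene_id))
  cat(sprintf("  R-squared %.3f, F(%d, %d) = %.3f, p = %.3g\n",
              x$r_squared, x$df_model, x$df_residual, x$model_f, x$model_p))
  if (length(x$aliased)) {
    cat("  aliased terms:", paste(x$aliased, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fit the factorial model to sporulation efficiencies
#'
#' Applies the same full factorial model to per-replicate phenotype
#' measurements. With the complete 16-strain, 4-replicate panel the residual
#' degrees of freedom are 64 - 16 = 48.
#'
#' @param phenotypes Data frame with `strain_id`, `replicate`, `efficiency`.
#' @param panel A `genotype_panel`.
#' @return A `model_fit` (see [fit_genotype_model()]) with
#'   `gene_id = "phenotype"`.
#' @export
fit_phenotype_model <- function(phenotypes, panel) {
  validate_panel(panel)
  need <- c("strain_id", "replicate", "efficiency")
  miss <- setdiff(need, names(phenotypes))
  if (length(miss)) {
    stop("phenotype table is missing column(s): ", paste(miss, collapse = ", "))
  }
  unknown <- setdiff(phenotypes$strain_id, panel$strain_id)
  if (length(unknown)) {
    stop("phenotype table refers to unknown strain(s): ",
         paste(unknown, collapse = ", "))
  }
  pseudo <- data.frame(
    sample_id = paste0(phenotypes$strain_id, "_r", phenotypes$replicate),
    strain_id = phenotypes$strain_id,
    day = "A",
    replicate = phenotypes$replicate,
    stringsAsFactors = FALSE
  )
  X <- build_design_matrix(panel, pseudo)
  fit_genotype_model(phenotypes$efficiency, X, gene_id = "phenotype")
}

#' Per-gene model p-values for a whole residual matrix
#'
#' Vectorized overall-F p-values of the factorial model applied to every gene
#' of a (day-residualized) expression matrix at once; used by the
#' permutation-null machinery and the pipeline. Zero-variance genes get p = 1.
#'
#' @param residuals Gene x sample numeric matrix.
#' @param design Design matrix with rows aligned to `colnames(residuals)`.
#' @param df_adjust Degrees of freedom consumed upstream (default: the
#'   `df_consumed` attribute left by [fit_day_residuals()], else 0).
#' @return Named numeric vector of model p-values, one per gene. The
#'   corresponding R-squared values are attached as `attr(, "r_squared")`.
#' @export
genomewide_model_p <- function(residuals, design,
                               df_adjust = attr(residuals, "df_consumed")) {
  if (is.null(df_adjust)) df_adjust <- 0L
  Y <- as.matrix(residuals)
  X <- as.matrix(design)
  if (ncol(Y) != nrow(X)) stop("design rows must match residual columns")
  qx <- qr(X)
  rank <- qx$rank
  n <- nrow(X)
  df_model <- rank - 1L
  df_residual <- n - rank - as.integer(df_adjust)
  if (df_residual < 1L) stop("no residual degrees of freedom")
  Yt <- t(Y)
  eff <- qr.qty(qx, Yt)
  rss <- colSums(eff[(rank + 1L):n, , drop = FALSE]^2)
  tss <- colSums(Yt^2) - colSums(Yt)^2 / n
  fstat <- ((tss - rss) / df_model) / (rss / df_residual)
  p <- stats::pf(fstat, df_model, df_residual, lower.tail = FALSE)
  degenerate <- tss <= .Machine$double.eps * n
  p[degenerate] <- 1
  r2 <- ifelse(degenerate, 0, 1 - rss / tss)
  names(p) <- rownames(Y)
  attr(p, "r_squared") <- stats::setNames(r2, rownames(Y))
  p
}
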