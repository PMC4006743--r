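#' Sequential (Type-I) ANOVA of a factorial model fit
#'
#' Decomposes the total sum of squares of a fitted factorial model into
#' per-term sequential sums of squares, added in design column order (main
#' effects first, then interactions of increasing order). Each term's SS is
#' computed from the orthogonalized QR effects of the design, which equals
#' the drop in residual SS when the term is added to the model containing
#' all preceding terms. F statistics test each term against the residual
#' mean square. With the complete balanced panel the centered effect columns
#' are orthogonal and the decomposition is order-invariant; with a missing
#' replicate it is (slightly) order-dependent, and the documented fixed
#' order is used.
#'
#' @param fit A `model_fit` from [fit_genotype_model()] or
#'   [fit_phenotype_model()].
#' @return An `anova_table`: data frame with columns `term`, `df`, `ss`,
#'   `ms`, `f`, `p`, `fraction` (percent of total SS, residual included in
#'   the denominator), one row per non-intercept term plus a `Residuals`
#'   row. With zero residual df, `f` and `p` are `NA`.
#' @export
sequential_anova <- function(fit) {
  stopifnot(inherits(fit, "model_fit"))
  X <- fit$design
  y <- fit$response
  n <- nrow(X)
  qx <- qr(X)
  rank <- qx$rank
  term_names <- colnames(X)[-1L]
  if (identical(qx$pivot, seq_len(ncol(X))) && rank == ncol(X)) {
    eff <- qr.qty(qx, y)
    ss <- eff[2:ncol(X)]^2
    rss <- if (n > rank) sum(eff[(rank + 1L):n]^2) else 0
  } else {
    # rank-deficient or pivoted design: fall back to explicit nested fits
    ss <- numeric(length(term_names))
    prev <- sum(stats::lm.fit(X[, 1L, drop = FALSE], y)$residuals^2)
    for (j in seq_along(term_names)) {
      rssj <- sum(stats::lm.fit(X[, seq_len(j + 1L), drop = FALSE],
                                y)$residuals^2)
      ss[j] <- prev - rssj
      prev <- rssj
    }
    rss <- prev
  }
  # residual df from the fit, which accounts for df consumed upstream
  anova_table(term = term_names, df = rep(1L, length(term_names)), ss = ss,
              residual_ss = rss, residual_df = fit$df_residual)
}

#' Assemble an ANOVA table from per-term df and sums of squares
#'
#' Computes mean squares, F statistics against the residual mean square,
#' F-distribution p-values and the per-term fraction of total variance
#' (percent of the total SS, residual included). Used both by
#' [sequential_anova()] and to re-derive the summary columns of a published
#' ANOVA table from its printed df and SS columns.
#'
#' @param term Character vector of term labels (excluding residuals).
#' @param df Integer vector of per-term degrees of freedom.
#' @param ss Numeric vector of per-term sums of squares.
#' @param residual_ss,residual_df Residual sum of squares and df.
#' @return An `anova_table` data frame: `term`, `df`, `ss`, `ms`, `f`, `p`,
#'   `fraction`, with a final `Residuals` row (`f`, `p` = `NA`).
#' @export
anova_table <- function(term, df, ss, residual_ss, residual_df) {
  stopifnot(length(term) == length(df), length(df) == length(ss))
  if (any(ss < -1e-8 * max(abs(ss), 1))) stop("sums of squares must be >= 0")
  ss <- pmax(ss, 0)
  total <- sum(ss) + residual_ss
  ms <- ss / df
  if (residual_df > 0L) {
    ms_res <- residual_ss / residual_df
    f <- ms / ms_res
    p <- stats::pf(f, df, residual_df, lower.tail = FALSE)
  } else {
    ms_res <- NA_real_
    f <- rep(NA_real_, length(ss))
    p <- rep(NA_real_, length(ss))
  }
  fraction <- if (total > 0) 100 * c(ss, residual_ss) / total else
    rep(NA_real_, length(ss) + 1L)
  out <- data.frame(
    term = c(term, "Residuals"),
    df = c(df, residual_df),
    ss = c(ss, residual_ss),
    ms = c(ms, ms_res),
    f = c(f, NA_real_),
    p = c(p, NA_real_),
    fraction = fraction,
    stringsAsFactors = FALSE
  )
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Per-term fraction of total variance
#'
#' `100 * ss / ss_total`, where the total includes the residual SS — the
#' convention under which the published per-term fractions and the headline
#' "fraction of variance explained" reproduce from the SS column.
#'
#' @param table An `anova_table` (or data frame with `term` and `ss`).
#' @return Named numeric vector of percents, one per row (including
#'   `Residuals`), summing to 100.
#' @export
fraction_of_variance <- function(table) {
  total <- sum(table$ss)
  if (!isTRUE(total > 0)) stop("degenerate input: total sum of squares is 0")
  stats::setNames(100 * table$ss / total, table$term)
}

is_interaction <- function(term) grepl(":", term, fixed = TRUE)

term_contains <- function(term, allele) {
  vapply(strsplit(term, ":", fixed = TRUE),
         function(parts) allele %in% parts, logical(1))
}

#' Per-allele main and interaction variance shares
#'
#' For each allele, sums the variance fractions of its significant terms
#' (term F-test p below `p_threshold`): the allele's own main effect, and
#' every significant interaction term whose label contains the allele.
#' Interaction terms involving several alleles are credited to each of them,
#' so shares overlap across alleles by design.
#'
#' @param table An `anova_table` with p-values.
#' @param alleles Allele (locus) labels; default: all main-effect terms in
#'   the table.
#' @param p_threshold Term significance threshold (default 0.1, a
#'   deliberately permissive cut for including factors).
#' @param gene_id Optional label attached to the rows.
#' @return Data frame with one row per allele: `allele`, `main_fraction`,
#'   `interaction_fraction`, `total_fraction` (percents),
#'   `n_significant_terms`.
#' @export
allele_shares <- function(table, alleles = NULL, p_threshold = 0.1,
                          gene_id = NULL) {
  tab <- table[table$term != "Residuals", , drop = FALSE]
  if (is.null(alleles)) alleles <- tab$term[!is_interaction(tab$term)]
  sig <- !is.na(tab$p) & tab$p < p_threshold
  out <- do.call(rbind, lapply(alleles, function(a) {
    main_row <- tab$term == a
    int_rows <- is_interaction(tab$term) & term_contains(tab$term, a)
    main_fr <- sum(tab$fraction[main_row & sig])
    int_fr <- sum(tab$fraction[int_rows & sig])
    data.frame(allele = a,
               main_fraction = main_fr,
               interaction_fraction = int_fr,
               total_fraction = main_fr + int_fr,
               n_significant_terms = sum((main_row | int_rows) & sig),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(gene_id)) out <- cbind(gene_id = gene_id, out)
  rownames(out) <- NULL
  out
}

#' Split explained variance into additive and interaction parts
#'
#' Sums the variance fractions of significant main-effect terms (the
#' additive part) and significant interaction terms, at the given term
#' p-value threshold. Because the published table footnotes appear to sum
#' all interaction rows rather than only significant ones, the
#' all-term sums are returned as well; neither convention is privileged.
#'
#' @param table An `anova_table` with p-values.
#' @param p_threshold Term significance threshold (default 0.1).
#' @return Named numeric vector: `additive`, `interaction` (significant
#'   terms only), `additive_all`, `interaction_all` (all terms), percents.
#' @export
additive_interaction_split <- function(table, p_threshold = 0.1) {
  tab <- table[table$term != "Residuals", , drop = FALSE]
  sig <- !is.na(tab$p) & tab$p < p_threshold
  inter <- is_interaction(tab$term)
  c(additive = sum(tab$fraction[!inter & sig]),
    interaction = sum(tab$fraction[inter & sig]),
    additive_all = sum(tab$fraction[!inter]),
    interaction_all = sum(tab$fraction[inter]))
}
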