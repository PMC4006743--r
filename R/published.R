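#' Published sporulation-efficiency ANOVA (df and SS columns)
#'
#' The per-term degrees of freedom and sequential sums of squares of the
#' published analysis of variance of sporulation efficiencies in the
#' sixteen-strain oak x vineyard allele-replacement panel (64 observations,
#' full four-locus factorial model). These two printed columns are inputs
#' from which [anova_table()] re-derives mean squares, F statistics,
#' p-values and variance fractions; the package does not hard-code any of
#' the derived summary values.
#'
#' @return An `anova_table` built from the printed df and SS columns via
#'   [anova_table()].
#' @examples
#' tab <- published_sporulation_anova()
#' round(fraction_of_variance(tab), 2)
#' @export
published_sporulation_anova <- function() {
  term <- c(
    "RME1nc", "RSF1c", "IME1c", "IME1nc",
    "RME1nc:RSF1c", "RME1nc:IME1c", "RME1nc:IME1nc",
    "RSF1c:IME1c", "RSF1c:IME1nc", "IME1c:IME1nc",
    "RME1nc:RSF1c:IME1c", "RME1nc:RSF1c:IME1nc",
    "RME1nc:IME1c:IME1nc", "RSF1c:IME1c:IME1nc",
    "RME1nc:RSF1c:IME1c:IME1nc"
  )
  ss <- c(7702.0, 4517.0, 7212.0, 1459.1,
          293.7, 134.3, 84.6, 118.6, 32.9, 124.6,
          161.4, 4.4, 136.3, 34.6, 0.1)
  anova_table(term = term, df = rep(1L, length(term)), ss = ss,
              residual_ss = 427.8, residual_df = 48L)
}
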