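# Shared fixtures: the canonical four-locus panel and small simulated
# datasets, all built in code under fixed seeds.

qtn_panel <- function() make_full_factorial_panel()

# A small day-structured count dataset with known truth.
small_dataset <- function(n_genes = 60, mode = "nb", seed = 101,
                          drop_strain = "VVOV") {
  panel <- qtn_panel()
  st <- make_sample_table(panel, drop_strain = drop_strain)
  truth <- expression_truth(n_genes, mode = mode, seed = seed)
  sim <- simulate_expression_counts(panel, st, truth, seed = seed + 1)
  list(panel = panel, samples = st, counts = sim$counts, truth = truth)
}

# Brute-force sequential SS oracle: fit each prefix model with lm.fit and
# difference the residual sums of squares.
nested_ss_oracle <- function(X, y) {
  p <- ncol(X)
  rss <- vapply(seq_len(p), function(j) {
    sum(stats::lm.fit(X[, seq_len(j), drop = FALSE], y)$residuals^2)
  }, numeric(1))
  rss0 <- sum(stats::lm.fit(X[, 1, drop = FALSE], y)$residuals^2)
  list(ss = c(rss0, rss[-p]) - rss, residual_ss = rss[p])
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of group
# assignments (no ties assumed); also returns the U statistic of x.
exact_wilcoxon_oracle <- function(x, y) {
  n1 <- length(x)
  nt <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(nt, n1)
  u_all <- apply(combos, 2, function(idx) {
    sum(rank(c(x, y))[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * length(y) / 2
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu))
  list(u = u_obs, p = p)
}
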