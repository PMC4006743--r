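test_that("sequential SS equals brute-force nested-model differences", {
  # 50 random small instances, incl. the unbalanced 63-sample layout
  panel <- qtn_panel()
  st63 <- make_sample_table(panel, drop_strain = "VVOV")
  X63 <- build_design_matrix(panel, st63)
  st64 <- make_sample_table(panel)
  X64 <- build_design_matrix(panel, st64)
  set.seed(401)
  for (i in 1:50) {
    X <- if (i %% 2) X63 else X64
    y <- rnorm(nrow(X), mean = 20, sd = 5)
    fit <- fit_genotype_model(y, X)
    tab <- sequential_anova(fit)
    oracle <- nested_ss_oracle(X, y)
    k <- nrow(tab) - 1
    expect_equal(tab$ss[1:k], oracle$ss[-1], tolerance = 1e-8)
    expect_equal(tab$ss[k + 1], oracle$residual_ss, tolerance = 1e-8)
  }
})

test_that("sequential ANOVA matches R's own anova() on an lm fit", {
  panel <- qtn_panel()
  st <- make_sample_table(panel, drop_strain = "VVOV")
  X <- build_design_matrix(panel, st)
  set.seed(402)
  y <- drop(X %*% rnorm(16, sd = 3)) + rnorm(63, sd = 2)
  tab <- sequential_anova(fit_genotype_model(y, X))
  dat <- as.data.frame(X[, -1])  # make.names turns ":" into "."
  dat$y <- y
  ref <- stats::anova(stats::lm(y ~ ., data = dat))
  expect_equal(tab$ss[1:15], head(ref$`Sum Sq`, 15), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(tab$p[1:15], head(ref$`Pr(>F)`, 15),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("constant responses yield all-zero term SS", {
  panel <- qtn_panel()
  st <- make_sample_table(panel, reps = 2)
  X <- build_design_matrix(panel, st)
  tab <- sequential_anova(fit_genotype_model(rep(7, 32), X))
  expect_equal(tab$ss[1:15], rep(0, 15), tolerance = 1e-18)
})

test_that("balanced panel decomposition is invariant to main-effect order", {
  panel <- qtn_panel()
  st <- make_sample_table(panel)
  set.seed(403)
  y <- rnorm(64, 50, 8)
  X <- build_design_matrix(panel, st)
  perm_loci <- c("IME1c", "RME1nc", "IME1nc", "RSF1c")
  Xp <- X[, c("(Intercept)", perm_loci,
              colnames(X)[!colnames(X) %in% c("(Intercept)", qtn_loci())])]
  ss1 <- sequential_anova(fit_genotype_model(y, X))
  ss2 <- sequential_anova(fit_genotype_model(y, Xp))
  for (l in qtn_loci()) {
    expect_equal(ss1$ss[ss1$term == l], ss2$ss[ss2$term == l],
                 tolerance = 1e-10)
  }
})

test_that("published df and SS reproduce the printed summary columns", {
  tab <- published_sporulation_anova()
  fr <- fraction_of_variance(tab)
  expect_equal(unname(round(fr[c("RME1nc", "RSF1c", "IME1c", "IME1nc")], 2)),
               c(34.32, 20.13, 32.13, 6.50))
  expect_equal(unname(round(fr["Residuals"], 2)), 1.91)
  expect_equal(sum(fr), 100, tolerance = 1e-12)
  expect_equal(round(tab$f[tab$term == "RME1nc"], 1), 864.2)
  # F for every term is ms / ms_residual
  ms_res <- tab$ms[tab$term == "Residuals"]
  expect_equal(tab$f[1:15], tab$ms[1:15] / ms_res, tolerance = 1e-12)
})

test_that("fraction_of_variance rejects a zero-SS table", {
  tab <- anova_table("A", 1L, 0, residual_ss = 0, residual_df = 3L)
  expect_error(fraction_of_variance(tab), "degenerate")
})

test_that("allele shares credit each allele's significant terms", {
  tab <- published_sporulation_anova()
  shares <- allele_shares(tab, p_threshold = 0.1)
  fr <- fraction_of_variance(tab)
  rme <- shares[shares$allele == "RME1nc", ]
  expect_equal(rme$main_fraction, unname(fr["RME1nc"]), tolerance = 1e-12)
  # significant RME1nc interactions at p < 0.1 (recomputed from df+SS):
  sig_int <- c("RME1nc:RSF1c", "RME1nc:IME1c", "RME1nc:IME1nc",
               "RME1nc:RSF1c:IME1c", "RME1nc:IME1c:IME1nc")
  expect_equal(rme$interaction_fraction, sum(fr[sig_int]), tolerance = 1e-12)
  expect_equal(rme$total_fraction,
               rme$main_fraction + rme$interaction_fraction)
  # a term naming several alleles is credited to each of them
  rsf <- shares[shares$allele == "RSF1c", ]
  expect_true("RME1nc:RSF1c" %in% sig_int)
  expect_gte(rsf$interaction_fraction, fr[["RME1nc:RSF1c"]])
})

test_that("nothing is credited when no term is significant", {
  tab <- anova_table(c("A", "B", "A:B"), rep(1L, 3), c(1, 2, 3),
                     residual_ss = 1000, residual_df = 10L)
  shares <- allele_shares(tab, p_threshold = 0.1)
  expect_equal(shares$total_fraction, rep(0, 2))
  split <- additive_interaction_split(tab)
  expect_equal(unname(split[c("additive", "interaction")]), c(0, 0))
})

test_that("simulated single-allele effects land on the right allele", {
  panel <- qtn_panel()
  truth <- phenotype_truth(60, c(RSF1c = -25), noise_sd = 2)
  shares <- lapply(1:10, function(s) {
    ph <- simulate_phenotypes(panel, truth, reps = 4, seed = 500 + s)
    allele_shares(sequential_anova(fit_phenotype_model(ph, panel)))
  })
  rsf <- sapply(shares, function(s) s$main_fraction[s$allele == "RSF1c"])
  others <- sapply(shares, function(s) max(s$total_fraction[s$allele !=
                                                              "RSF1c"]))
  expect_gt(mean(rsf), 90)
  expect_lt(mean(others), 5)
})

test_that("additive plus interaction plus residual partitions the variance", {
  tab <- published_sporulation_anova()
  split <- additive_interaction_split(tab, p_threshold = 0.1)
  expect_equal(unname(round(split["additive"], 2)), 93.08)
  fr <- fraction_of_variance(tab)
  nonsig <- sum(fr) - split[["additive"]] - split[["interaction"]] -
    fr[["Residuals"]]
  expect_equal(split[["additive"]] + split[["interaction"]] + nonsig +
                 fr[["Residuals"]], 100, tolerance = 1e-10)
  # all-term sums reproduce the full additive/interaction partition
  expect_equal(split[["additive_all"]] + split[["interaction_all"]] +
                 fr[["Residuals"]], 100, tolerance = 1e-10)
})

test_that("per-term fraction recovery is unbiased at the panel design", {
  panel <- qtn_panel()
  target <- c(RME1nc = 34, RSF1c = 20, IME1c = 32, IME1nc = 6.5)
  truth <- phenotype_truth_from_fractions(target)
  fr <- sapply(1:50, function(s) {
    ph <- simulate_phenotypes(panel, truth, reps = 4, seed = 600 + s)
    tab <- sequential_anova(fit_phenotype_model(ph, panel))
    tab$fraction[match(names(target), tab$term)]
  })
  expect_lt(max(abs(rowMeans(fr) - target)), 3)
  # interaction shares of a main-effects-only truth stay near zero
  int_fr <- sapply(1:20, function(s) {
    ph <- simulate_phenotypes(panel, truth, reps = 4, seed = 700 + s)
    split <- additive_interaction_split(
      sequential_anova(fit_phenotype_model(ph, panel)))
    split[["interaction"]]
  })
  expect_lt(mean(int_fr), 3)
})
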