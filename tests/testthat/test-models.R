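test_that("design matrix uses oak-reference treatment coding in fixed order", {
  panel <- qtn_panel()
  X <- build_design_matrix(panel)
  expect_equal(dim(X), c(16, 16))
  expect_equal(colnames(X)[1:5],
               c("(Intercept)", "RME1nc", "RSF1c", "IME1c", "IME1nc"))
  expect_equal(colnames(X)[6], "RME1nc:RSF1c")
  expect_equal(colnames(X)[16], "RME1nc:RSF1c:IME1c:IME1nc")
  # all-oak row is the reference, all-vineyard row is all ones
  expect_equal(unname(X["OOOO", ]), c(1, rep(0, 15)))
  expect_equal(unname(X["VVVV", ]), rep(1, 16))
  # interaction columns are products of their main columns
  expect_equal(X[, "RME1nc:IME1c"], X[, "RME1nc"] * X[, "IME1c"])
  expect_equal(X[, "RME1nc:RSF1c:IME1c:IME1nc"],
               X[, "RME1nc"] * X[, "RSF1c"] * X[, "IME1c"] * X[, "IME1nc"])
  expect_equal(qr(X)$rank, 16)
})

test_that("per-sample design rows follow the strain lookup and reject unknowns", {
  panel <- qtn_panel()
  st <- make_sample_table(panel, drop_strain = "VVOV")
  X <- build_design_matrix(panel, st)
  expect_equal(nrow(X), 63)
  expect_equal(rownames(X), st$sample_id)
  st_bad <- st
  st_bad$strain_id[1] <- "QQQQ"
  expect_error(build_design_matrix(panel, st_bad), "absent from the panel")
})

test_that("day residualization removes exactly the day structure", {
  panel <- qtn_panel()
  st <- make_sample_table(panel)
  # single day: residuals are counts minus the gene mean
  st1 <- make_sample_table(panel, reps = 2, days = c("A", "A"))
  m <- matrix(rnorm(3 * 32, mean = 100), nrow = 3,
              dimnames = list(paste0("g", 1:3), st1$sample_id))
  res1 <- fit_day_residuals(m, st1)
  expect_equal(res1, m - rowMeans(m), tolerance = 1e-12, ignore_attr = TRUE)

  # counts built as gene mean + known day offsets, zero noise: residuals 0
  offs <- c(A = 0, B = 30, C = -10, D = 5)
  m2 <- matrix(rep(c(100, 200), 64), nrow = 2, byrow = FALSE,
               dimnames = list(c("g1", "g2"), st$sample_id))
  m2 <- sweep(m2, 2, offs[st$day], `+`)
  res2 <- fit_day_residuals(m2, st)
  expect_equal(max(abs(res2)), 0, tolerance = 1e-10)

  # residuals are orthogonal to the day indicators (OLS normal equations)
  set.seed(7)
  m3 <- matrix(rnorm(5 * 64, 50, 10), nrow = 5,
               dimnames = list(paste0("g", 1:5), st$sample_id))
  res3 <- fit_day_residuals(m3, st)
  D <- stats::model.matrix(~ factor(st$day))
  expect_equal(max(abs(res3 %*% D)), 0, tolerance = 1e-8)
  # and per gene they sum to ~0 within each day level
  for (d in unique(st$day)) {
    expect_equal(max(abs(rowSums(res3[, st$day == d]))), 0,
                 tolerance = 1e-8)
  }
})

test_that("empty day levels are rejected", {
  panel <- qtn_panel()
  st <- make_sample_table(panel, reps = 2, days = c("A", "B"))
  st$day <- factor(st$day, levels = c("A", "B", "C"))
  m <- matrix(1, 2, nrow(st), dimnames = list(c("g1", "g2"), st$sample_id))
  expect_error(fit_day_residuals(m, st), "day level")
})

test_that("genotype model recovers exact coefficients and handles degeneracy", {
  panel <- qtn_panel()
  st <- make_sample_table(panel, reps = 2)
  X2 <- build_design_matrix(panel, st)
  beta <- seq(-8, 7)
  y <- drop(X2 %*% beta)
  fit <- fit_genotype_model(y, X2)
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$df_residual, 16)

  # a saturated design (one replicate) leaves no residual df and is refused
  expect_error(fit_genotype_model(rnorm(16), build_design_matrix(panel)),
               "too few observations")

  # zero response: documented convention
  fit0 <- fit_genotype_model(rep(0, 32), X2)
  expect_equal(unname(fit0$coefficients), rep(0, 16))
  expect_equal(fit0$r_squared, 0)
  expect_equal(fit0$model_p, 1)
})

test_that("coefficients are invariant to response mean shift except intercept", {
  panel <- qtn_panel()
  st <- make_sample_table(panel, reps = 2)
  X <- build_design_matrix(panel, st)
  set.seed(8)
  y <- rnorm(32, 10, 4)
  f1 <- fit_genotype_model(y, X)
  f2 <- fit_genotype_model(y + 100, X)
  expect_equal(f1$coefficients[-1], f2$coefficients[-1], tolerance = 1e-9)
  expect_equal(unname(f2$coefficients[1] - f1$coefficients[1]), 100,
               tolerance = 1e-9)
})

test_that("null model p-values are uniform over simulations", {
  # calibration: random gaussian response, 63 obs, 16-term model
  panel <- qtn_panel()
  st <- make_sample_table(panel, drop_strain = "VVOV")
  X <- build_design_matrix(panel, st)
  set.seed(99)
  Y <- matrix(rnorm(2000 * 63), nrow = 2000,
              dimnames = list(sprintf("s%04d", 1:2000), st$sample_id))
  p <- genomewide_model_p(Y, X)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # vectorized p agrees with the one-gene fit path
  f1 <- fit_genotype_model(Y[17, ], X)
  expect_equal(unname(p[17]), f1$model_p, tolerance = 1e-10)
})

test_that("log-variant model includes day covariates and demands nonnegativity", {
  panel <- qtn_panel()
  st <- make_sample_table(panel)
  X <- build_design_matrix(panel, st)
  set.seed(10)
  y <- rpois(64, 100)
  fit <- fit_genotype_model(y, X, response_transform = "log", day = st$day)
  expect_true(any(grepl("^DAY", names(fit$coefficients))))
  expect_equal(fit$df_residual, 64 - 16 - 3)
  expect_error(fit_genotype_model(c(-1, y[-1]), X,
                                  response_transform = "log", day = st$day),
               "nonnegative")
  # oracle: same fit via lm with explicit formula
  dat <- data.frame(y = log(y + 1), X[, -1], day = st$day,
                    check.names = FALSE)
  lmfit <- stats::lm(y ~ ., data = dat)
  expect_equal(fit$r_squared, summary(lmfit)$r.squared, tolerance = 1e-10)
})

test_that("phenotype model on the full panel has 48 residual df", {
  panel <- qtn_panel()
  truth <- phenotype_truth_from_fractions(
    c(RME1nc = 34, RSF1c = 20, IME1c = 32, IME1nc = 6.5))
  ph <- simulate_phenotypes(panel, truth, reps = 4, seed = 5)
  fit <- fit_phenotype_model(ph, panel)
  expect_equal(fit$df_residual, 48)
  expect_equal(fit$df_model, 15)
  # internal consistency: R^2 equals 1 - SS_res/SS_tot of its own ANOVA
  tab <- sequential_anova(fit)
  expect_equal(fit$r_squared,
               1 - tab$ss[tab$term == "Residuals"] / sum(tab$ss),
               tolerance = 1e-10)

  # zero-noise synthetic phenotypes: perfect fit
  ph0 <- simulate_phenotypes(panel,
                             phenotype_truth(60, c(RME1nc = -10), 0),
                             reps = 2, seed = 1)
  expect_equal(fit_phenotype_model(ph0, panel)$r_squared, 1,
               tolerance = 1e-12)
})

test_that("balanced-panel centered main-effect columns are orthogonal", {
  panel <- qtn_panel()
  st <- make_sample_table(panel)
  X <- build_design_matrix(panel, st)
  mains <- scale(X[, qtn_loci()], scale = FALSE)
  off <- crossprod(mains)
  diag(off) <- 0
  expect_equal(max(abs(off)), 0, tolerance = 1e-10)
})
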