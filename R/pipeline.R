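#' Pipeline run configuration
#'
#' Collects input paths and the analysis parameters with their standard
#' defaults: 20% low-expression filter, 10% FDR, term-inclusion p < 0.1,
#' 1000 permutations recording the 5th percentile, identity response scale.
#' A YAML file with the same keys can be loaded with [read_run_config()];
#' explicit arguments override file values.
#'
#' @param counts,samples,genotypes Paths to the input TSVs (required).
#' @param phenotypes Optional phenotype TSV path.
#' @param out_dir Output directory for pipeline artifacts.
#' @param filter_quantile Low-expression filter fraction in \[0, 1).
#' @param fdr BH false discovery rate in (0, 1\].
#' @param term_p_threshold ANOVA term inclusion threshold in (0, 1\].
#' @param n_perm Permutation replicates (0 skips the permutation stage).
#' @param percentile Genome-wide p-value percentile in (0, 1).
#' @param reference_day Day label anchoring the multiplicative day
#'   correction for CV summaries.
#' @param seed Integer seed for the permutation stage.
#' @param response_transform `"identity"` (two-stage day residualization)
#'   or `"log"` (one-stage log model with day covariates).
#' @return A `run_config` list.
#' @export
run_config <- function(counts, samples, genotypes, phenotypes = NULL,
                       out_dir = "qtnvar_out", filter_quantile = 0.20,
                       fdr = 0.10, term_p_threshold = 0.1, n_perm = 1000L,
                       percentile = 0.05, reference_day = "A", seed = 1L,
                       response_transform = c("identity", "log")) {
  response_transform <- match.arg(response_transform)
  if (filter_quantile < 0 || filter_quantile >= 1) {
    stop("'filter_quantile' must be in [0, 1)")
  }
  if (fdr <= 0 || fdr > 1) stop("'fdr' must be in (0, 1]")
  if (term_p_threshold <= 0 || term_p_threshold > 1) {
    stop("'term_p_threshold' must be in (0, 1]")
  }
  if (percentile <= 0 || percentile >= 1) {
    stop("'percentile' must be in (0, 1)")
  }
  if (n_perm < 0) stop("'n_perm' must be >= 0")
  structure(list(
    paths = list(counts = counts, samples = samples, genotypes = genotypes,
                 phenotypes = phenotypes),
    out_dir = out_dir,
    filter_quantile = filter_quantile,
    fdr = fdr,
    term_p_threshold = term_p_threshold,
    n_perm = as.integer(n_perm),
    percentile = percentile,
    reference_day = reference_day,
    seed = as.integer(seed),
    response_transform = response_transform
  ), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()]
#'   (input paths at top level or under `paths:`).
#' @param ... Overrides applied on top of the file values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$paths)) {
    raw <- c(raw$paths, raw[setdiff(names(raw), "paths")])
  }
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  known <- names(formals(run_config))
  do.call(run_config, raw[intersect(names(raw), known)])
}

stage_log <- function(stage, ...) {
  message(sprintf("[qtnvar:%s] %s", stage, sprintf(...)))
}

#' Run the full variance-decomposition pipeline
#'
#' Composes the analysis stages in their canonical order: read and validate
#' inputs, median-of-ratios normalization, low-expression filtering, per-gene
#' day residualization (or the one-stage log model), per-gene factorial
#' model fits, BH FDR control plus (optionally) the genotype-permutation
#' genome-wide threshold, sequential ANOVA decomposition with per-allele
#' shares for the significant genes, day-corrected CV summaries, and the
#' phenotype model when phenotypes are provided. All result tables are
#' written as TSV under `config$out_dir` together with a run manifest; the
#' run is deterministic given `config$seed`. Any stage failure aborts with
#' a stage-tagged error.
#'
#' @param config A `run_config`.
#' @return Invisibly, the result bundle: `size_factors`, `filtered_counts`,
#'   `fits` (per-gene model summary data frame), `anova_long`,
#'   `allele_shares`, `bh`, `permutation` (or `NULL`), `cv_expression`,
#'   `cv_phenotype`/`phenotype_fit`/`phenotype_anova` (if phenotypes given),
#'   and `paths` of the written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out_path <- function(f) file.path(config$out_dir, f)
  paths <- list()

  stage_log("read", "reading input tables")
  inputs <- run_stage("read", read_tables(config))
  counts <- inputs$counts
  samples <- inputs$samples
  panel <- inputs$panel

  stage_log("normalize", "median-of-ratios size factors for %d samples",
            ncol(counts))
  sf <- run_stage("normalize", compute_size_factors(counts))
  norm <- run_stage("normalize", normalize_counts(counts, sf))
  paths$size_factors <- out_path("size_factors.tsv")
  write_size_factors(sf, paths$size_factors)

  stage_log("filter", "removing lowest %.0f%% of %d genes",
            100 * config$filter_quantile, nrow(norm))
  filtered <- run_stage("filter",
                        filter_low_expression(norm, config$filter_quantile))
  stage_log("filter", "%d genes remain", nrow(filtered))
  paths$filtered_counts <- out_path("filtered_counts.tsv")
  write_count_matrix(filtered, paths$filtered_counts)

  design <- run_stage("fit", build_design_matrix(panel, samples))
  samples_in <- samples[match(colnames(filtered), samples$sample_id), ]

  if (config$response_transform == "identity") {
    stage_log("fit", "per-gene day residualization, then factorial models")
    residuals <- run_stage("fit", fit_day_residuals(filtered, samples_in))
    day_df <- attr(residuals, "df_consumed")
    fit_one <- function(g) {
      fit_genotype_model(residuals[g, ], design, df_adjust = day_df,
                         gene_id = g)
    }
  } else {
    stage_log("fit", "one-stage log models with day covariates")
    residuals <- NULL
    fit_one <- function(g) {
      fit_genotype_model(filtered[g, ], design, response_transform = "log",
                         day = samples_in$day, gene_id = g)
    }
  }
  genes <- rownames(filtered)
  fits <- run_stage("fit", lapply(genes, fit_one))
  names(fits) <- genes
  fit_tab <- do.call(rbind, lapply(fits, function(f) {
    coefs <- f$coefficients[colnames(design)]
    data.frame(gene_id = f$gene_id, t(coefs), r_squared = f$r_squared,
               model_f = f$model_f, model_p = f$model_p,
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  rownames(fit_tab) <- NULL
  paths$model_fits <- out_path("model_fits.tsv")
  utils::write.table(fit_tab, paths$model_fits, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  stage_log("significance", "BH FDR control at %.0f%%", 100 * config$fdr)
  model_p <- vapply(fits, function(f) f$model_p, numeric(1))
  bh <- run_stage("significance", bh_adjust(model_p, fdr = config$fdr))
  stage_log("significance", "%d of %d gene models significant",
            sum(bh$significant), nrow(bh))
  paths$bh_results <- out_path("bh_results.tsv")
  utils::write.table(bh, paths$bh_results, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  permutation <- NULL
  if (config$n_perm > 0L && config$response_transform == "identity") {
    stage_log("permute", "%d genotype permutations (seed %d)",
              config$n_perm, config$seed)
    permutation <- run_stage("permute", permutation_threshold(
      residuals, samples_in, panel, n_perm = config$n_perm,
      percentile = config$percentile, seed = config$seed))
    paths$permutation_null <- out_path("permutation_null.tsv")
    utils::write.table(as.data.frame(permutation), paths$permutation_null,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    stage_log("permute", "permutation stage skipped (n_perm = %d, %s scale)",
              config$n_perm, config$response_transform)
  }

  stage_log("decompose", "sequential ANOVA for %d significant genes",
            sum(bh$significant))
  sig_genes <- bh$gene_id[bh$significant]
  anova_long <- NULL
  shares <- NULL
  if (length(sig_genes)) {
    tabs <- run_stage("decompose", lapply(sig_genes, function(g) {
      tab <- sequential_anova(fits[[g]])
      cbind(gene_id = g, tab)
    }))
    anova_long <- do.call(rbind, tabs)
    rownames(anova_long) <- NULL
    shares <- do.call(rbind, lapply(tabs, function(tab) {
      allele_shares(tab[, -1L], alleles = panel_loci(panel),
                    p_threshold = config$term_p_threshold,
                    gene_id = tab$gene_id[1L])
    }))
    paths$anova_long <- out_path("anova_long.tsv")
    utils::write.table(anova_long, paths$anova_long, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$allele_shares <- out_path("allele_shares.tsv")
    utils::write.table(shares, paths$allele_shares, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  stage_log("cv", "day-corrected replicate CVs (reference day %s)",
            config$reference_day)
  corrected <- run_stage("cv", day_correct_counts(filtered, samples_in,
                                                  config$reference_day))
  cv_expr <- run_stage("cv", expression_cv(corrected, samples_in))
  paths$cv_expression <- out_path("cv_expression.tsv")
  utils::write.table(cv_expr, paths$cv_expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  result <- list(size_factors = sf, filtered_counts = filtered,
                 fits = fit_tab, bh = bh, permutation = permutation,
                 anova_long = anova_long, allele_shares = shares,
                 cv_expression = cv_expr, paths = paths)

  if (!is.null(inputs$phenotypes)) {
    stage_log("phenotype", "factorial model of sporulation efficiencies")
    pfit <- run_stage("phenotype", fit_phenotype_model(inputs$phenotypes,
                                                       panel))
    panova <- sequential_anova(pfit)
    paths$phenotype_anova <- out_path("phenotype_anova.tsv")
    utils::write.table(panova, paths$phenotype_anova, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cv_ph <- phenotype_cv(inputs$phenotypes)
    paths$cv_phenotype <- out_path("cv_phenotype.tsv")
    utils::write.table(cv_ph, paths$cv_phenotype, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    result$phenotype_fit <- pfit
    result$phenotype_anova <- panova
    result$cv_phenotype <- cv_ph
    result$paths <- paths
  }

  manifest <- c(
    "qtnvar pipeline run",
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("package_version: ",
           as.character(utils::packageVersion("qtnvar"))),
    paste0("seed: ", config$seed),
    paste0("filter_quantile: ", config$filter_quantile),
    paste0("fdr: ", config$fdr),
    paste0("term_p_threshold: ", config$term_p_threshold),
    paste0("n_perm: ", config$n_perm),
    paste0("percentile: ", config$percentile),
    paste0("reference_day: ", config$reference_day),
    paste0("response_transform: ", config$response_transform),
    paste0("genes_in: ", nrow(counts)),
    paste0("genes_after_filter: ", nrow(filtered)),
    paste0("significant_genes: ", sum(bh$significant))
  )
  writeLines(manifest, out_path("run_manifest.txt"))
  result$paths$manifest <- out_path("run_manifest.txt")

  stage_log("done", "all stages complete; outputs in %s", config$out_dir)
  invisible(result)
}
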