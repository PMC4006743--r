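#' @name io
#' @title Tab-separated readers and writers for pipeline artifacts
#'
#' @description All tabular artifacts are plain TSV with a header row: count
#' matrices are gene-rows with a leading `gene_id` column; sample, genotype,
#' phenotype and size-factor tables are one row per record. Readers validate
#' structure and report the file, line and field of the first problem;
#' writers produce files the corresponding readers round-trip exactly.
#'
#' @param path File path.
#' @param counts Gene x sample numeric matrix.
#' @param panel A `genotype_panel`.
#' @param sample_table,phenotypes,factors The corresponding objects.
#' @param loci Locus labels expected in a genotype table.
NULL

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    stop(what, " file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  tab
}

#' @rdname io
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), as.data.frame(counts),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_count_matrix <- function(path) {
  tab <- read_tsv_checked(path, "gene_id", "count matrix")
  if (anyDuplicated(tab$gene_id)) {
    stop("count matrix ", path, ": duplicate gene_id at line ",
         which(duplicated(tab$gene_id))[1L] + 1L)
  }
  m <- as.matrix(tab[, setdiff(names(tab), "gene_id"), drop = FALSE])
  if (!is.numeric(m)) stop("count matrix ", path, ": non-numeric values")
  if (any(m < 0)) stop("count matrix ", path, ": negative values")
  rownames(m) <- tab$gene_id
  m
}

#' @rdname io
#' @export
write_sample_table <- function(sample_table, path) {
  utils::write.table(sample_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_sample_table <- function(path) {
  tab <- read_tsv_checked(path, c("sample_id", "strain_id", "day",
                                  "replicate"), "sample table")
  tab$day <- as.character(tab$day)
  validate_sample_table(tab)
  tab
}

#' @rdname io
#' @export
write_genotype_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_genotype_panel <- function(path, loci = NULL) {
  tab <- read_tsv_checked(path, "strain_id", "genotype table")
  if (is.null(loci)) loci <- setdiff(names(tab), "strain_id")
  miss <- setdiff(loci, names(tab))
  if (length(miss)) {
    stop("genotype table ", path, " is missing locus column(s): ",
         paste(miss, collapse = ", "))
  }
  for (l in loci) {
    bad <- which(!tab[[l]] %in% c("O", "V"))
    if (length(bad)) {
      stop("genotype table ", path, ": invalid allele code '",
           tab[[l]][bad[1L]], "' at line ", bad[1L] + 1L, ", field ", l)
    }
  }
  if (anyDuplicated(tab$strain_id)) {
    stop("genotype table ", path, ": duplicate strain_id at line ",
         which(duplicated(tab$strain_id))[1L] + 1L)
  }
  panel <- tab[, c("strain_id", loci)]
  attr(panel, "loci") <- loci
  class(panel) <- c("genotype_panel", "data.frame")
  panel
}

#' @rdname io
#' @export
write_phenotype_table <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_phenotype_table <- function(path) {
  tab <- read_tsv_checked(path, c("strain_id", "replicate", "efficiency"),
                          "phenotype table")
  bad <- which(tab$efficiency < 0 | tab$efficiency > 100)
  if (length(bad)) {
    stop("phenotype table ", path, ": efficiency outside [0, 100] at line ",
         bad[1L] + 1L)
  }
  tab
}

#' @rdname io
#' @export
write_size_factors <- function(factors, path) {
  utils::write.table(
    data.frame(sample_id = names(factors), factor = as.numeric(factors)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_size_factors <- function(path) {
  tab <- read_tsv_checked(path, c("sample_id", "factor"), "size factor")
  if (any(tab$factor <= 0)) stop("size factor file ", path,
                                 ": non-positive factor")
  stats::setNames(tab$factor, tab$sample_id)
}

#' Read and cross-validate all pipeline inputs
#'
#' Loads the count matrix, sample table, genotype panel and (optionally)
#' phenotype table named by a run configuration and checks their
#' cross-references: every count column has a sample-table row, every
#' sample's strain is in the panel, allele codes are `O`/`V`.
#'
#' @param config A `run_config` (see [run_config()]).
#' @return List with `counts`, `samples`, `panel` and (if configured)
#'   `phenotypes`.
#' @export
read_tables <- function(config) {
  counts <- read_count_matrix(config$paths$counts)
  samples <- read_sample_table(config$paths$samples)
  panel <- read_genotype_panel(config$paths$genotypes)
  validate_panel(panel)
  validate_sample_table(samples, panel)
  missing <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing)) {
    stop("count matrix samples absent from sample table: ",
         paste(missing, collapse = ", "))
  }
  out <- list(counts = counts, samples = samples, panel = panel)
  if (!is.null(config$paths$phenotypes)) {
    phen <- read_phenotype_table(config$paths$phenotypes)
    unknown <- setdiff(phen$strain_id, panel$strain_id)
    if (length(unknown)) {
      stop("phenotype table refers to unknown strain(s): ",
           paste(unknown, collapse = ", "))
    }
    out$phenotypes <- phen
  }
  out
}

#' Write a simulated dataset to disk
#'
#' Generates a full synthetic dataset (panel, sample table, counts,
#' phenotypes, truth) under one seed and writes each piece as TSV together
#' with a run-manifest echoing the parameters, so the file-based pipeline
#' can be exercised end to end without external data.
#'
#' @param dir Output directory (created if needed).
#' @param n_genes Number of genes to simulate.
#' @param seed Master seed (truth and draws are derived from it).
#' @param mode Count simulator mode, `"nb"` or `"gaussian"`.
#' @param drop_strain Strain losing one replicate (default `"VVOV"`, giving
#'   the 63-sample layout; `NULL` keeps all 64).
#' @param ... Further arguments to [expression_truth()].
#' @return Invisibly, the named list of written paths.
#' @export
write_synthetic_dataset <- function(dir, n_genes = 200L, seed = 1L,
                                    mode = "nb", drop_strain = "VVOV", ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- make_full_factorial_panel()
  samples <- make_sample_table(panel, drop_strain = drop_strain)
  truth <- expression_truth(n_genes, mode = mode, seed = seed, ...)
  sim <- simulate_expression_counts(panel, samples, truth, seed = seed + 1L)
  ph_truth <- phenotype_truth_from_fractions(
    c(RME1nc = 34, RSF1c = 20, IME1c = 32, IME1nc = 6.5))
  phen <- simulate_phenotypes(panel, ph_truth, reps = 4L, seed = seed + 2L)
  paths <- list(
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    genotypes = file.path(dir, "genotypes.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    truth = file.path(dir, "truth_effects.tsv"),
    manifest = file.path(dir, "manifest.txt")
  )
  write_count_matrix(sim$counts, paths$counts)
  write_sample_table(samples, paths$samples)
  write_genotype_panel(panel, paths$genotypes)
  write_phenotype_table(phen, paths$phenotypes)
  truth_tab <- data.frame(gene_id = truth$gene_id,
                          intercept = truth$intercept,
                          truth$beta, check.names = FALSE)
  utils::write.table(truth_tab, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c(
    "qtnvar synthetic dataset",
    paste0("seed: ", seed),
    paste0("n_genes: ", n_genes),
    paste0("mode: ", mode),
    paste0("samples: ", nrow(samples)),
    paste0("dropped_strain: ", if (is.null(drop_strain)) "none" else
      drop_strain)
  ), paths$manifest)
  invisible(paths)
}
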