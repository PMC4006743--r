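#' The four sporulation QTN loci
#'
#' Default locus labels for the oak x vineyard allele-replacement panel:
#' the non-coding RME1 variant (`RME1nc`), the RSF1 coding variant (`RSF1c`),
#' and the IME1 coding (`IME1c`) and non-coding (`IME1nc`) variants.
#'
#' @return Character vector of four locus labels, in canonical model order.
#' @export
qtn_loci <- function() {
  c("RME1nc", "RSF1c", "IME1c", "IME1nc")
}

#' Enumerate a full factorial allele-replacement panel
#'
#' Builds the panel of all `2^L` strains carrying every combination of the
#' oak (`"O"`) and vineyard (`"V"`) alleles at `L` biallelic loci. Strain ids
#' are the allele strings in locus order (e.g. `"OOOO"`, `"OVVO"`). The order
#' is deterministic: oak before vineyard, with the last locus varying fastest,
#' so the first strain is all-oak and the last is all-vineyard.
#'
#' @param loci Character vector of 1 to 8 distinct locus labels.
#' @return A `genotype_panel`: a data frame with a `strain_id` column and one
#'   `"O"`/`"V"` column per locus, `2^L` rows, with the locus labels stored in
#'   `attr(, "loci")`.
#' @examples
#' make_full_factorial_panel(c("A", "B"))
#' nrow(make_full_factorial_panel())  # 16 strains
#' @export
make_full_factorial_panel <- function(loci = qtn_loci()) {
  if (!is.character(loci) || length(loci) < 1L || length(loci) > 8L) {
    stop("'loci' must be a character vector of 1 to 8 locus labels")
  }
  if (anyDuplicated(loci)) {
    stop("duplicate locus labels: ",
         paste(unique(loci[duplicated(loci)]), collapse = ", "))
  }
  # expand.grid varies the first column fastest; feed loci reversed so the
  # last locus varies fastest, then restore column order
  grid <- expand.grid(rep(list(c("O", "V")), length(loci)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(grid) <- rev(loci)
  grid <- grid[, loci, drop = FALSE]
  panel <- cbind(
    data.frame(strain_id = apply(grid, 1L, paste0, collapse = ""),
               stringsAsFactors = FALSE),
    grid
  )
  rownames(panel) <- NULL
  attr(panel, "loci") <- loci
  class(panel) <- c("genotype_panel", "data.frame")
  panel
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("Genotype panel: %d strains x %d loci (%s)\n",
              nrow(x), length(panel_loci(x)),
              paste(panel_loci(x), collapse = ", ")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Locus labels of a genotype panel
#'
#' @param panel A `genotype_panel` (or any data frame with allele columns and
#'   a `loci` attribute).
#' @return Character vector of locus labels.
#' @export
panel_loci <- function(panel) {
  loci <- attr(panel, "loci")
  if (is.null(loci)) loci <- setdiff(names(panel), "strain_id")
  loci
}

validate_panel <- function(panel) {
  loci <- panel_loci(panel)
  if (!all(c("strain_id", loci) %in% names(panel))) {
    stop("genotype panel must have 'strain_id' and one column per locus")
  }
  if (anyDuplicated(panel$strain_id)) stop("strain ids must be distinct")
  alleles <- unlist(panel[loci], use.names = FALSE)
  bad <- setdiff(unique(alleles), c("O", "V"))
  if (length(bad)) {
    stop("allele codes must be 'O' or 'V'; found: ",
         paste(bad, collapse = ", "))
  }
  invisible(panel)
}

#' Build a replicate sample table for a panel
#'
#' Lays out `reps` biological replicates per strain, each replicate batch
#' grown on its own day (day labels `"A"`, `"B"`, ... by default), mirroring
#' an experiment where the whole panel is processed together and repeated on
#' successive days. Optionally drops one replicate of one strain, as happens
#' when a library fails: the study design this emulates has 63 expression
#' samples because one strain yielded only 3 usable libraries.
#'
#' @param panel A `genotype_panel`.
#' @param reps Replicates per strain (default 4).
#' @param days Day label per replicate batch; length `reps`.
#' @param drop_strain Optional `strain_id` that loses one replicate
#'   (default `NULL` keeps the design complete).
#' @param drop_replicate Which replicate of `drop_strain` to drop (default
#'   the last).
#' @return Data frame with columns `sample_id`, `strain_id`, `day`,
#'   `replicate`.
#' @examples
#' panel <- make_full_factorial_panel()
#' nrow(make_sample_table(panel))                         # 64
#' nrow(make_sample_table(panel, drop_strain = "VVOV"))   # 63
#' @export
make_sample_table <- function(panel, reps = 4L, days = LETTERS[seq_len(reps)],
                              drop_strain = NULL, drop_replicate = reps) {
  validate_panel(panel)
  reps <- as.integer(reps)
  if (reps < 1L) stop("'reps' must be >= 1")
  if (length(days) != reps) stop("'days' must have one label per replicate")
  tab <- expand.grid(replicate = seq_len(reps), strain_id = panel$strain_id,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- tab[, c("strain_id", "replicate")]
  tab$day <- as.character(days)[tab$replicate]
  tab$sample_id <- paste0(tab$strain_id, "_r", tab$replicate)
  if (!is.null(drop_strain)) {
    if (!drop_strain %in% panel$strain_id) {
      stop("drop_strain '", drop_strain, "' is not in the panel")
    }
    keep <- !(tab$strain_id == drop_strain & tab$replicate == drop_replicate)
    tab <- tab[keep, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab[, c("sample_id", "strain_id", "day", "replicate")]
}

validate_sample_table <- function(sample_table, panel = NULL) {
  need <- c("sample_id", "strain_id", "day", "replicate")
  miss <- setdiff(need, names(sample_table))
  if (length(miss)) {
    stop("sample table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(sample_table$sample_id)) stop("sample ids must be unique")
  if (is.factor(sample_table$day) &&
      any(table(sample_table$day) == 0L)) {
    stop("day level with no samples: ",
         paste(names(which(table(sample_table$day) == 0L)), collapse = ", "))
  }
  if (!is.null(panel)) {
    unknown <- setdiff(sample_table$strain_id, panel$strain_id)
    if (length(unknown)) {
      stop("sample table refers to strain(s) absent from the panel: ",
           paste(unknown, collapse = ", "))
    }
  }
  invisible(sample_table)
}
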