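Package: qtnvar
Title: Variance Decomposition for Factorial QTN Allele-Replacement Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how individual quantitative trait nucleotides (QTN)
    and their genetic interactions explain variation in gene expression and in
    a downstream quantitative phenotype, using a full-factorial
    allele-replacement panel design. Provides median-of-ratios count
    normalization and low-expression filtering, per-gene batch (day-of-growth)
    residualization, full four-locus factorial linear models, sequential
    (Type-I) ANOVA with per-allele main and interaction variance shares,
    Benjamini-Hochberg FDR control, a genotype-permutation genome-wide
    significance threshold, replicate-noise (CV) summaries, and a
    negative-binomial / gaussian count simulator with known ground truth so
    that the entire pipeline can be exercised and calibrated without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    withr
Config/testthat/edition: 3
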