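---
title: "Decomposing expression and phenotype variance over a factorial QTN panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing expression and phenotype variance over a factorial QTN panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtnvar)
```

## The setting

An allele-replacement panel makes the usual eQTL identifiability problems
disappear: all 2⁴ combinations of the oak (O) and vineyard (V) alleles at
four causative loci (`RME1nc`, `RSF1c`, `IME1c`, `IME1nc`) are engineered
into one isogenic background, so *any* reproducible variation in gene
expression or in sporulation efficiency across the sixteen strains must be
caused by those four nucleotides. The analysis question is purely one of
attribution: how much variance does each allele explain, directly and
through genetic interactions, in each gene's expression and in the
phenotype?

## The model and its assumptions

Every response is fit by ordinary least squares on the full factorial
design with **treatment (dummy) coding**: the vineyard allele is the
indicator (x = 1), oak is the reference, interaction columns are products
of main columns. The intercept is therefore the all-oak strain mean and
each coefficient is the effect of swapping vineyard alleles into that
background. Sum-to-zero coding is deliberately not offered: the per-gene
model coefficients are meant to read as "expression change caused by the
vineyard allele(s)", and the variance decomposition below is coding-
independent in the balanced case.

Sequential (Type-I) ANOVA attributes to each term the drop in residual sum
of squares when it joins the model, in a fixed order: main effects
(`RME1nc`, `RSF1c`, `IME1c`, `IME1nc`), then two-way, three-way and the
four-way interaction. On the complete balanced panel the centered effect
columns are orthogonal and the attribution is order-invariant (the test
suite asserts this); with the one missing expression library it is very
slightly order-dependent, and the fixed documented order is the contract.
A term's *fraction of variance explained* is `100 · SS/SS_total` with the
residual SS included in the total — the convention under which the shipped
published table's fractions reproduce exactly from its SS column.

Assumptions worth keeping in mind: homoscedastic gaussian errors within
the linear models (expression counts are analyzed on the identity scale by
default, as in the original analysis; a `log(N+1)` variant with day
covariates is provided for comparison), day effects additive on the
modeling scale, and no genetic variation beyond the four loci.

## Two-stage day correction and degrees of freedom

Expression models are fit in two stages: per gene, OLS residuals against
the day-of-growth factor, then the factorial model on those residuals. Day
is a property of the sample, not the genotype, which is also why the
permutation null (below) permutes genotypes *after* residualization.

One numerical subtlety is handled explicitly. Residualizing against
`d` days consumes `d − 1` degrees of freedom beyond the grand mean; a
second-stage F-test that ignores this uses a residual df of `n − 16` when
only `n − 16 − (d − 1)` independent residual dimensions remain, and its
null p-values are detectably anticonservative (a KS test against uniform
fails at a few hundred genes). `fit_day_residuals()` therefore records the
consumed df on its result and the downstream fits subtract it, so the
two-stage p-values are calibrated (63 samples, 4 days: F on 15 and 44 df).
This is a deliberate refinement of the naive lm-on-residuals recipe; it
changes per-gene p-values only slightly and leaves all SS, fractions and
the phenotype model (which has no day stage) untouched.

## Significance: FDR and the permutation check

Per-gene overall-model p-values are adjusted by Benjamini–Hochberg and
called at FDR 10% (both configurable). As an independent genome-wide check,
`permutation_threshold()` reassigns the strain labels of the samples —
keeping each sample's four alleles together as an intact genotype vector,
so the null preserves the within-strain allele correlation — refits every
gene, and records the 5th percentile of the genome-wide p distribution;
1000 replicates (100 at test scale) give its null distribution. Signal is
indicated when the observed percentile falls well below the null mean,
about two standard deviations in the motivating study's decision rule. The
permutation is not stratified by day by default (the day structure is
already removed from the residuals); a within-day-stratified option exists
for sensitivity analysis. Each replicate runs on its own seed derived from
the master seed, so the replicate set is order-insensitive and
reproducible.

## Normalization and filtering conventions

Size factors are the median over genes of the ratio of a gene's count to
its across-sample geometric mean, using only genes with strictly positive
counts in every sample (a zero anywhere makes the geometric mean zero);
excluded genes are still normalized and filterable. The low-expression
filter removes the `ceiling(q · G)` genes with the smallest total
normalized counts, ties broken by gene label for determinism — the
convention under which a 5792-gene genome retains exactly 4633 genes at
q = 0.20. Filtering at q = 0 is the identity and larger q keeps a subset,
both asserted as properties.

## What the simulator emulates — and what it does not

`make_sample_table()` lays out 4 replicates per strain, each replicate
batch grown on its own day (A–D), and can drop one replicate of one strain;
the default expression layout drops replicate 4 of strain `VVOV`
(vineyard at `RME1nc`, `RSF1c`, `IME1nc`; oak at `IME1c`), giving the
63-sample design of the motivating study. Which strain lost its library is
configurable since only its genotype is known.

`expression_truth()`/`simulate_expression_counts()` draw counts either as
negative binomial (`mean = day_multiplier · exp(intercept + Xβ)`,
`variance = μ + μ²/size`, the standard RNA-seq overdispersion form;
multiplicative day effects, matching the ratio-style day correction) or as
rounded, zero-floored gaussians with additive day offsets (matching the
residual-subtraction correction, and the mode used for calibration tests
because its null is exactly gaussian). Defaults: 5% of genes affected,
log-scale main effects of SD 0.5 with two-way interactions at half that,
NB size 10, day multipliers `exp(N(0, 0.15))` — typical magnitudes for
well-replicated bulk RNA-seq in yeast. The simulator does *not* emulate
read-level sampling, GC/length bias, correlated gene modules, or
count-depth interactions beyond the size-factor mechanism, so passing
recovery tests demonstrates correctness of the inference machinery, not
robustness to every artifact of real libraries.

For phenotypes, `phenotype_truth_from_fractions()` inverts the balanced-
design expectation `E[SS_main] = N b²/4 + σ²`, `E[SS_total] =
Σ N b²/4 + (N − 1)σ²` to find main-effect sizes that hit target variance
fractions — the study condition used throughout testing is
(34, 20, 32, 6.5)% at 16 strains × 4 replicates. The default intercept
(90%) and replicate noise (SD 4 percentage points) were chosen once so all
sixteen cell means sit well inside [0, 100]: efficiencies are clipped to
that range, and a truth pushed against the boundaries would truncate the
noise and bias the recovered SS. The real panel's extreme parents (≈100%
and ≈3.5% sporulation) cannot be represented by a mains-only truth with
those fractions without such clipping; representing the fraction structure
faithfully was preferred over representing the raw means.

## Numerical choices and degenerate inputs

* Zero-variance response: reported as `r_squared = 0`, `model_p = 1`
  (avoids 0/0); a constant response likewise yields all-zero term SS.
* Rank-deficient designs are fit with pivoting; aliased coefficients are
  reported as `NA` and sequential SS fall back to explicit nested refits.
* Sequential SS are computed from the QR effects vector; tests require
  agreement with brute-force nested-model refits to 1e-8 relative.
* CV uses the sample (n − 1) standard deviation over the mean, on
  day-corrected counts on the original scale (ratio correction, anchored
  at a required reference day), not on residuals — scale matters for a
  ratio statistic. Zero means are flagged undefined rather than infinite.
* The rank-sum comparison of two alleles' per-gene share profiles uses the
  normal approximation with tie and continuity correction; it matches
  exhaustive U enumeration on the statistic exactly and on p to a few
  percent at n ≤ 8.
* In `additive_interaction_split()`, both significant-only and all-term
  sums are reported: published summaries of this design ambiguously mix
  the two conventions (their printed additive total uses significant terms;
  their printed interaction total only reproduces as the all-term sum), so
  neither is privileged.

## Problem sizes

The test and acceptance runs use deliberately modest sizes chosen for tight
feedback loops: 500 genes × 63 samples with 100 permutations for null
calibration, 200 null datasets of 200 genes for the FDR check, 20–50 seeds
for recovery, and 2000 simulated genes for the uniformity check. All scale
linearly if rerun at genome size.

## Known limitations

Identity-scale OLS on counts ignores the mean-variance relation of RNA-seq
(a count GLM is out of scope by design — the aim is a faithful, calibrated
implementation of the linear-model analysis); the permutation machinery
provides a genome-wide threshold only, not per-gene permutation p-values;
and Type-II/III decompositions, REML variance components and heritability
are intentionally absent.
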