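---
title: "Methods: gene-level LOF association and expression analysis in two-cohort studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-level LOF association and expression analysis in two-cohort studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lofassoc)
```

`lofassoc` implements the downstream statistics of a two-cohort
sequencing comparison — typically two small, closed livestock
populations genotyped from RNA-seq — from variant QC through gene-level
loss-of-function (LOF) burden analysis, population structure and
differential expression.  This vignette is the package's account of the
models it fits, the defaults it ships, and the choices made where the
design was genuinely open.

## Study design and containers

The canonical design is two cohorts, labelled A and B, of about seven
diploid individuals each.  Genotypes live in a `genotype_table`
(samples x variants dosage matrix plus sample and variant sheets);
expression lives in an `expression_table` (genes x samples counts or
TPM).  Dosages are oriented **once**, on the combined sample, so that
the counted allele is the globally rarer one; a frequency tie at
exactly 0.5 keeps the ALT orientation.  The orientation is never
redone per cohort, so a cohort-level frequency contrast always refers
to the same allele.

## Variant QC

`apply_variant_qc()` applies the standard cascade, each step logged in
a telescoping `QcLedger`:

* **call rate** — keep iff strictly greater than 0.90.  The two
  conventional phrasings (">90%" and "exclude <90%") differ only at
  exactly 0.90, where the stricter reading is used, one rule
  everywhere.
* **MAF** — combined-sample minor allele frequency >= 0.01.
* **HWE** — exact test (`hwe_exact_test()`, full enumeration of
  heterozygote counts given allele counts; two-sided by summing
  configurations no more probable than the observed one).  A variant is
  removed only when it fails at 5e-8 in **both** cohorts; a
  `hwe_rule = "either"` switch is provided because the literal "both"
  convention is unusual and a reader may want the stricter rule.

Gene-level testing units come from `select_lof_gene_sets()`: variants
in one of the seven LOF classes (frameshift and non-frameshift
indels, nonsynonymous SNVs, stop gains/losses), call rate > 0.90,
unambiguously assigned to exactly one gene; genes with at least two
such variants are kept.

## Single-variant scan and genomic control

`run_single_variant_scan()` runs the classical allelic 2x2 Fisher
exact test per variant (two-sided by the probability-ordering
convention, identical to `fisher.test`).  The genomic-control factor is
`lambda_gc = median(qchisq(1 - p, 1)) / 0.4549364`.  With fourteen
samples, allele-count tests are discrete and conservative, so
`lambda_gc` well below 1 on null data is expected and is not evidence
of a fault; a value far above 1 indicates structure or differentiation.
The corrected p-value column (`gc_correct = TRUE`) divides each
chi-squared quantile by lambda; it is reported but never used to select
genes downstream.

## Gene-level LOF association

For each gene, minor/major allele counts are collapsed over its
variants into a 2x2 table (`gene_crosstab()`), tested by Pearson's
chi-squared **without** continuity correction (a Yates flag exists).
The odds ratio uses the Woolf log-normal interval with
`z = 1.959964`; any zero cell returns the `Null` convention rather
than a Haldane-Anscombe correction — this exactly reproduces a
validated reference table of 30 gene rows (23 numeric, 7 Null) in the
test-suite regression.

The score tests operate on the per-variant dosage matrix under the
intercept-only binary null (`skat_null_model()`: fitted mean = cohort-B
fraction, working variance `mu(1-mu)`), with Beta(1, 25) MAF weights:

* **Burden** — squared weighted-sum score, a 1-df test.
* **SKAT** — variance-component score `Q = r' G W^2 G' r` with the
  weighted chi-squared mixture null; mixture tails via the
  Liu four-moment match (`quadform_pvalue()`, default) or Imhof's
  characteristic-function inversion (`method = "imhof"`).
* **SKAT-O** — `Q_rho = (1-rho) Q_SKAT + rho Q_Burden` over the grid
  {0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1}, combining the minimum
  per-rho p-value by the standard one-dimensional integration over the
  shared common factor.

**Small-sample null.** At n = 14 the asymptotic mixture null is
visibly wrong in the body of the distribution (measured deviations of
0.03-0.14 in p against the exact permutation null), because the
conditional null given the observed case count differs from the
unconditional Bernoulli null and no central limit has taken hold.  The
reference implementations of these tests apply small-sample
adjustments in exactly this regime.  `lofassoc` goes one step further:
when the number of distinct case/control assignments is enumerable
(`choose(n, n_cases) <= 20000`; 3432 for 7 vs 7), the p-value is the
**exact conditional tail probability** over all assignments
(`exact = "auto"`, the default).  SKAT-O enumerates the null of its
minimum-p statistic, ranking assignments by the same fixed Liu
transform applied to the observed data, so the grid endpoints still
reduce exactly to SKAT and Burden.  The asymptotic path remains
available (`exact = "never"`) and is what larger designs use
automatically.  Consequences worth knowing: exact p-values are
discrete with minimum `1/choose(n, k)` (about 2.9e-4 at 7 vs 7), so a
14-sample study can never reach a 1.84e-5 Bonferroni threshold through
the score tests — only through the collapsed chi-squared, which uses
allele counts rather than individuals.

Multiple testing uses Bonferroni `alpha / n_genes` on the chi-squared
column (with a suggestive tier at `p_chi < 1e-4`), and the gene-scan
lambda is likewise computed from `p_chi` only.

## Population structure

* `ibs_distance()` — pairwise `1 - mean(1 - |g_i - g_j| / 2)` over
  variants called in both samples.
* `pca_genotypes()` — smartPCA-style normalisation: posterior (add-one)
  allele frequency, centring on the observed mean,
  `sqrt(2 p (1-p))` scaling, missing set to 0 after centring,
  monomorphic columns dropped; coordinates from the SVD, each component
  sign-stabilised so the first sample's coordinate is non-negative.
  A plain-MLE frequency mode is available by flag.
* `detect_outliers_pca()` — flags samples >= `n_sd` cohort SDs from
  their cohort mean on PC1/PC2.  Flagging only; removal is an explicit
  pipeline option (`remove_outliers`), mirroring how a PCA outlier in a
  real study is a recorded analyst decision, never automatic.
* `neighbor_joining()` — Saitou-Nei agglomeration with the
  Studier-Keppler criterion; ties broken by lexicographically smallest
  cluster-label pair; negative branch lengths clamped to zero with the
  deficit moved to the sister branch; final unrooted trifurcation.
  Exact on additive matrices (property-tested against random trees).
* `observed_heterozygosity()` — per-sample heterozygote fraction,
  averaged per cohort.

## Differential expression

Counts convert to TPM (`tpm_from_counts()`; per-kilobase rates scaled
to one million per sample).  Per gene, a two-group mean model on
`log2(TPM + 1)` gives the log2 fold change (B minus A) and pooled
residual variance on `n_A + n_B - 2` df.  Whether the upstream model
should see log TPM or log counts is genuinely ambiguous in this
field's practice; log2(TPM + 1) is the default and
`response = "log2_count"` is provided.  The pseudocount is 1.

`ebayes_moderate()` estimates the scaled inverse chi-squared prior
(d0, s0^2) by the log-variance moment method (digamma/trigamma
matching, monotone root-finding for d0; d0 = Inf when the observed
spread does not exceed sampling noise, in which case s0^2 is the
geometric mean of the variances).  The estimator agrees with
`limma::fitFDist` to 1e-6 on recovery simulations, and limma serves as
an independent oracle in the tests, never as the implementation.
Moderated t statistics use `d0 + dg` degrees of freedom (normal when
d0 is infinite).

Significance combines a raw p-value below alpha with the **adaptive
fold-change threshold** `T = mean(|lfc|) + 2 sd(|lfc|)` computed over
the full fitted fold-change vector before any flagging; a second tier
applies the same rule with BH-adjusted p-values.  The threshold is
always the formula, never a hard-coded constant.  Gene-set
overrepresentation (`ora_hypergeometric()`) is a plain upper-tail
hypergeometric test over user-supplied GMT sets intersected with the
tested universe, BH-corrected across sets; no annotation database is
bundled or queried.

## The synthetic-study generator

`simulate_study()` provides the package's study conditions:

* **Genotypes** — Balding-Nichols: ancestral MAF uniform on
  (0.05, 0.5); cohort frequencies Beta-distributed around it with
  variance `F p (1-p)` (`fst`, default 0.1; `fst = 0` shares the
  ancestral frequency exactly); genotypes Binomial(2, freq); 2%
  missingness.  Around 300 LOF-carrying genes with
  `1 + Poisson(3)` stopgain variants each (mean 4, so some genes fail
  the >= 2 filter on purpose) plus 2000 neutral variants.
* **Planted associations** — a signed allele-frequency shift added to
  cohort B for a chosen gene's variants, clipped to [0.01, 0.99].
  Recovery experiments plant **negative** shifts (depletion in cohort
  B): a positive shift pushes combined frequencies past 0.5, the
  minor-allele re-orientation then flips part of the gene's variants,
  and the collapsed counts cancel — a property of collapsed-count
  tests worth knowing about, not a bug.
* **Expression** — log-normal baseline means (meanlog 4, sdlog 1),
  negative binomial counts with dispersion 0.1, uniform gene lengths
  500-5000 bp; 100 of 10,000 genes DE with |log2FC| ~ Normal(4, 0.5)
  and random sign.

What the generator does **not** emulate: linkage disequilibrium,
RNA-seq expression-dependent genotype missingness, shared library-size
effects, batch structure, relatedness within cohorts.  Passing tests
therefore demonstrate statistical correctness of the machinery under
idealised sampling, not robustness to those real-data artefacts.

## Calibration experiments and problem sizes

The test suite fixes its simulation scales to keep a full run modest
on one CPU while leaving sampling error well inside the asserted
bands: 500 null genes for the chi-squared type-I band (binomial 95%
half-width ~0.019), 50 seeds for planted-gene top-rank recovery
(fst = 0 background, shift -0.5, >= 5 markers; measured 90%), 10,000
permutations for the score-test agreement checks (the exact
enumeration agrees within ~0.005), 5,000 genes for d0/s0^2 recovery,
20 seeds for planted-DE recovery, 15 random trees (<= 12 leaves) for
neighbour-joining.  Recovery is measured on an undifferentiated
background because with `fst = 0.1` the "top rank" contest is against
extreme Balding-Nichols background draws — that measures the
background model, not the plant.

## Numerical details and degenerate inputs

* Fisher and HWE tie comparisons use relative tolerances (1e-7 /
  1e-12) on the "no more probable" inequality; summed tails are capped
  at 1.
* `quadform_pvalue()` clamps to (1e-300, 1]; Imhof integration
  truncates where the polynomially-decaying envelope falls below
  1e-13.
* Zero margins: chi-squared returns statistic 0 / p 1 with a warning;
  Fisher likewise; zero-variance collapsed burden p = 1 with a
  warning; all-missing genes error.
* Monomorphic variants are dropped by PCA; all-monomorphic input is an
  error.
* NJ ties are resolved deterministically (lexicographic label pairs),
  so trees are reproducible across platforms.
* Every generator call seeds the RNG itself (`seed`, `seed + 1`), so
  identical configs give byte-identical tables wherever they are
  called.

## Known limitations

Exact score-test p-values are bounded below by enumeration
granularity; no covariates or kinship in the null model; no genotype
imputation beyond per-variant mean imputation inside the score tests;
IBS/NJ and PCA assume biallelic dosages; the DE model is a two-group
mean contrast, not a full design-matrix linear model.
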