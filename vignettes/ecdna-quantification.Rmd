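---
title: "Methods: quantifying ecDNA heterogeneity across cells, images and cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying ecDNA heterogeneity across cells, images and cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecdnatools)
```

Extrachromosomal DNA (ecDNA) amplifications segregate randomly at mitosis,
producing extreme cell-to-cell copy-number variance within a single tumor.
This vignette documents the statistical models implemented in `ecdnatools`,
the assumptions behind them, the tunable parameters and their defaults, and
the design decisions taken where the methodology was genuinely open.

## 1. Per-cell amplification calling from snATAC fragments

### Model

Let a cell have fragment set $F$ and let an amplicon $A$ be a union of
half-open genomic segments with total footprint $L_A$ bp. The test
statistic is the length-scaled coverage
$x = \#\{f \in F : f \cap A \neq \emptyset\} / L_A$ (fragments per bp; a
fragment counts once regardless of its duplicate-collapsed support, so PCR
copies are never double counted). Under the null of no focal amplification,
$x$ is exchangeable with the cell's coverage at a random genomic region of
the same length, because ATAC fragment density is (to first order)
proportional to genomic length for a diploid background.

The null is built by Monte Carlo: $n$ random contiguous regions of length
$L_A$ (default $n = 1000$) are drawn uniformly over all admissible
placements — on one chromosome, disjoint from an exclusion set containing
centromeres, telomeres, low-mappability regions and **all** declared
amplicons. Chromosomes are weighted by admissible start space so placement
is uniform genome-wide. The same $n$ regions are used for every cell: this
makes per-cell ranks comparable across cells, costs one sampler draw per
amplicon, and is what makes the per-amplicon BH step defensible (all cells
share one null geometry).

The empirical p-value is $\hat p = (r+1)/(n+1)$ with
$r = \#\{x^{null}_i \ge x\}$. Ties count as exceeding, which keeps $\hat p$
conservative and bounded in $[1/(n+1), 1]$; a cell with zero fragments gets
$\hat p = 1$. The per-cell z-score uses the sample standard deviation
(denominator $n-1$) of the null coverages; when the null is degenerate
(zero variance) the z-score is returned as `NA` with an `indeterminate`
flag rather than an infinity. Benjamini–Hochberg adjustment is applied
across cells **separately per amplicon** and a cell is called positive at
$q < 0.10$. Pooling BH across amplicons would couple unrelated null
geometries; per-amplicon adjustment matches the way co-occurrence counts
are reported (none / each single amplicon / each combination, a partition
of cells).

### Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `n_permutations` | 1000 | regions | p-value floor 1/1001 ≈ 1e-3, enough for q < 0.10 at thousands of cells |
| `q_threshold` | 0.10 | FDR | the conventional discovery threshold for this assay |
| `region_length_mode` | match_amplicon | — | null regions share the amplicon's total footprint; per-bp scaling then compares like with like |
| QC: mito fraction | < 0.1 | — | standard multiome quality gate |
| QC: ATAC fragments | 1,000–70,000 | fragments | excludes empty droplets and aggregates |
| QC: RNA counts | 500–25,000 | transcripts | applied only when the RNA modality is present |

Multi-segment amplicons are treated as the union of their segments and
matched by a single contiguous null region of the summed length: total
footprint is what the scaled-coverage statistic sees, and segment-matched
sampling would require arbitrary choices about segment spacing. Whether
real analyses length-match their random regions is an open point; per-bp
scaling makes the statistic comparable either way, and the mode is exposed
for future extension.

The mitochondrial fraction uses total fragments as denominator (fragments
on the configured `chrM` over all fragments), the common convention.
Doublet removal is deliberately out of scope: callers should pass
pre-filtered barcodes.

## 2. FISH spot counting

### Detector

1. Convolve the 0–255 image with a sampled Gaussian kernel, σ = 3 px,
   7×7, normalized to sum 1, reflective borders.
2. Threshold the convolved image at 15 (on 0–255).
3. Keep 8-connected components whose **peak raw** intensity exceeds the
   image-wide mean + 1 SD.
4. Drop components smaller than `min_area` pixels (default 4).

Each surviving component is one spot; spots are assigned to the nucleus
containing their centroid pixel, and a cell with strictly more than 5
spots is classified amplified. The relative threshold in step 3 is
computed image-wide (not per nucleus): FISH background is a property of
the field of view, and per-nucleus statistics would let a single bright
nucleus mask its own spots. `min_area` has no canonical published value;
4 px is the smallest area that reliably kills single-pixel noise after
σ = 3 smoothing while keeping true spots, whose post-convolution
footprint at the default amplitude is tens of pixels.

Connected components are *not* declumped: two spots whose smoothed
footprints merge above threshold count as one. This is a documented
limitation of peak-threshold detectors; the synthetic generator therefore
enforces a minimum spot separation (below), and real images with densely
packed signals will undercount.

The bundled `fallback_segment()` (Otsu threshold, hole fill, components,
≥ 500 px nuclei) exists for synthetic fixtures and smoke tests only;
touching nuclei merge, and production masks should come from a dedicated
segmentation tool.

Heterogeneity between a tumor and a reference line is summarized by the
two-sided Mann–Whitney rank-sum test (location) and Levene's test centred
on group means (scale), plus the amplified fraction per sample. The Levene
statistic is computed directly as the one-way ANOVA F on absolute
deviations from group means; when the deviations have no between-group
spread at all (e.g. a sample identical to the reference) the statistic is
defined as 0 with p = 1, where generic ANOVA code would return 0/0.

## 3. Sample fingerprinting

Variant allele fractions (alt/(ref+alt)) at a fixed SNP panel are
correlated between all sample pairs over loci observed (depth ≥
`min_depth`) in both. Same-patient pairs are flagged at r > 0.80. Two
guards handle missing data, which published procedures leave unstated:
pairs sharing fewer than `min_shared = 100` co-observed loci, and pairs
involving a sample with zero VAF variance, are reported *indeterminate*
rather than given a correlation — a handful of loci can produce spuriously
high r.

## 4. Cohort statistics

**Cox regression** maximizes the Efron-tie log partial likelihood minus a
ridge penalty $(\lambda/2)\lVert\beta\rVert^2$ by Newton–Raphson with step
halving (convergence at penalized gradient norm < 1e-8, max 100
iterations; non-convergence is flagged, never silent). Efron tie handling
is the modern default and matters for day-granularity survival times.
Confidence intervals come from the penalized observed-information
covariance. The penalty is selected by grid search
($\lambda \in \{0, 0.01, 0.1, 1, 10, 100\}$ by default) on fivefold
cross-validation, scoring each fold by the **unpenalized** withheld log
partial likelihood; ties resolve to the smallest $\lambda$, and folds
without events are skipped with a warning. Ridge estimation exists to
stabilize collinear covariates — TP53 alteration and ecDNA status co-occur
strongly — not to do variable selection. Covariates enter on their natural
scale; categorical covariates are dummy coded against the largest category
unless a reference is declared, and records with any missing covariate are
dropped (no imputation). One subtlety of Efron ties: duplicating every
record does not leave the estimate *exactly* invariant (it does under
Breslow, where doubling only shifts the likelihood by a constant);
duplication creates ties and moves the Efron estimate slightly, which the
test suite documents by comparing against the reference implementation on
the duplicated data.

**AFT regression** fits $\log T = X\beta + \sigma\varepsilon$,
$\varepsilon \sim N(0,1)$, by maximum likelihood (censored records
contribute survival-function terms), and reports each coefficient's
percentage change in survival time $100(e^{\hat\beta_k}-1)$. The
log-normal AFT — not Cox — is used for **Baron–Kenny mediation** because
hazard ratios are non-collapsible: comparing Cox coefficients with and
without the mediator confounds mediation with a change of baseline. Three
models are fitted (mediator ~ exposure by logistic regression; outcome ~
exposure, the total effect; outcome ~ exposure + mediator, the direct
effect) and the attenuation $1 - \beta_{direct}/\beta_{total}$ is reported
(defined only for nonzero total effect). A constant mediator, or a
mediator identical to the exposure, is an error naming the variable.

**2×2 association tests.** The χ² test applies the Yates continuity
correction by default, which is what reproduces the published subgroup
statistic (7.66) from the printed counts. Fisher's exact test returns the
standard two-sided p-value: the total probability of tables with the
observed margins no more probable than the observed one. A `midp = TRUE`
variant is provided (strictly less probable tables count fully, equally
probable ones half). The mid-p variant exists because published exact
p-values are sometimes mid-p without saying so: for the TP53-vs-ecDNA
table bundled in `fixture_tables()` the standard two-sided value is
2.6e-7 while the mid-p value is 1.3e-7 — exactly the value printed in the
source analysis. The default remains the standard test, which is what the
enumeration oracle in the test suite checks.

## 5. Synthetic data: what it emulates, what it does not

All generators are pure functions of a configuration and a seed
(byte-identical reruns) and every emitted file parses through the package
readers.

**Fragments** (`gen_fragments()`): a toy genome (3 × 10 Mbp autosomes +
chrM) with per-cell background fragments placed uniformly (Poisson mean
5,000 per cell), two amplicons (50 kb contiguous; 25 + 15 kb two-segment),
and, for the 10% of cells positive per amplicon, extra amplicon fragments
bringing the local per-bp rate to $k/2$ times the cell's background rate
at copy number $k$ (integer log-normal, median 20, minimum 5).
Mitochondrial fragments follow a Beta(4, 76) per-cell fraction (mean 0.05,
rarely above the 0.1 QC gate). The linear rate-in-$k$ model is the
simplest one consistent with length-scaled coverage; GC and mappability
bias, chromatin structure, doublets and ambient fragments are *not*
simulated, so passing tests demonstrate calibration of the statistics
under the model's own null, not robustness to those real-data artifacts.
The toy genome keeps a full 2,000-cell, 1,000-permutation run around half
a minute.

**FISH images** (`gen_fish_image()`): disjoint disk nuclei (radius 36–44
px on a 1000×1000 canvas), per-cell spot counts from a Poisson mixture
(mean 2 background, mean 20 amplified, 30% amplified), spots rendered as
σ = 3 px Gaussian peaks of amplitude 40 with a global minimum pairwise
separation of 16 px, optional additive Gaussian noise, 8-bit rounding.
Amplitude and separation were chosen once against the detector's fixed
thresholds: at amplitude 40 the smoothed peak (≈ 0.71 × amplitude ≈ 28)
clears the fixed threshold 15 with a wide margin, while the smoothed
value midway between two spots 16 px apart (≈ 0.11 × amplitude ≈ 4.5)
stays far below it, so spots neither vanish nor merge; with noise SD 5 the
post-convolution noise SD is ≈ 0.9, leaving > 10 SD of margin on both
sides. If a spot cannot be placed at the required separation after
bounded retries the count is reduced and the *achieved* count recorded as
truth. Real FFPE images — uneven background, optical blur, clustered
signals, sectioning artifacts — are deliberately out of scope; the images
validate the counting chain, not image restoration.

**Fingerprints** (`gen_fingerprints()`): Hardy–Weinberg genotypes (VAF 0,
0.5, 1) at panel allele frequencies drawn uniform on (0.2, 0.8), binomial
read counts at Poisson depth 30 with 1% allele error, duplicate samples
sharing their patient's genotype. The frequency range is restricted to
common, highly variable sites — as fingerprinting panels are in practice —
because the shared allele-frequency structure induces a baseline VAF
correlation of roughly $\mathrm{Var}(f) / (\mathrm{Var}(f) +
\mathbb{E}[f(1-f)]/2)$ between unrelated patients: ≈ 0.43 for frequencies
spanning (0.05, 0.95), uncomfortably close to common duplicate thresholds,
versus ≈ 0.21 for (0.2, 0.8), giving clean separation between same-patient
(r ≈ 0.97 at depth 30) and cross-patient pairs.

**Cohorts** (`gen_cohort()`): exposure Bernoulli(0.25), mediator from
logit$^{-1}(a_0 + a_1 E)$ (defaults −2, 3), log-normal AFT survival
$\log T = 7.0 - 0.4E - 0.9M + 0.8\,\varepsilon$ in log-days, uniform
censoring on (0, 4000) days (≈ 28% censored). The mediator effect size
(time ratio $e^{-0.9} \approx 0.41$) mirrors the strongly adverse
prognosis reported for ecDNA+ tumors. Decoy covariates (subgroup, age,
sex) have no effect on survival and exist to exercise dummy coding.
`gen_cohort_ph()` generates the complementary proportional-hazards world
(exponential baseline, true hazard ratio 2.5, ≈ 30% censoring at the
default window) for validating Cox coefficient recovery.

## 6. Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally (BED/fragments
  convention); abutting intervals never overlap.
* `foverlaps`-based counting converts half-open to closed intervals by
  subtracting 1 bp from ends (all coordinates integral), and materializes
  only integer id pairs so 10-million-fragment inputs stay in memory.
* Newton iterations use step halving to guarantee ascent; a singular
  information matrix aborts the iteration and flags non-convergence.
* `empirical_pvalue` on an empty null, `zscore` on fewer than two nulls,
  BH on p-values outside [0, 1], zero-margin 2×2 tables, mediation with a
  constant or exposure-identical mediator, and fitters on event-free data
  all raise informative errors rather than returning numbers.
* Constant images pass through normalization with a warning; blank images
  yield zero spots and empty masks yield empty count tables.

## 7. Problem sizes

The test and acceptance runs use 2,000 cells × 1,000 permutations for the
caller (with a 500-cell fully negative cohort for calibration), three
images of 10 nuclei per noise regime for FISH, cohorts of 500–2,000
patients for survival recovery, and a 20-patient, 1,000-locus panel with
two duplicate pairs for fingerprinting — sizes at which each statistic's
sampling error is comfortably inside the margins being asserted, while a
full run stays at desk scale.

## 8. Known limitations

* The caller assumes a uniform-coverage diploid background; broad
  chromosomal gains inflate coverage genome-wide and are absorbed into
  the null only insofar as null regions sample them.
* No doublet handling; a doublet of an ecDNA+ and an ecDNA− cell will be
  called positive.
* Spot counting undercounts merged spots and does not model 3-D stacks or
  multichannel data; mechanism classification (ecDNA vs HSR) is out of
  scope and recorded as unknown.
* Fingerprinting assumes a shared panel and comparable depth; it detects
  identity, not relatedness.
* The AFT/mediation machinery assumes log-normal survival and binary
  exposure/mediator; time-varying covariates and competing risks are out
  of scope.
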