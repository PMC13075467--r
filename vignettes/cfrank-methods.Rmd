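---
title: "Inferring blood cell-of-origin from cfDNA TSS coverage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring blood cell-of-origin from cfDNA TSS coverage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfrank)
library(dplyr)
```

## The biological signal

Plasma cell-free DNA (cfDNA) is released mostly by dying hematopoietic
cells. Because nucleosomes protect DNA from nuclease digestion, the
fragmentation pattern of cfDNA records the chromatin of the cells it came
from: actively transcribed genes are nucleosome-depleted around their
transcription start site (TSS), so the TSS windows of genes expressed in
the contributing cells show *reduced* cfDNA coverage, while silent genes
stay uniformly covered.

`cfrank` turns this into a relative cell-of-origin readout in three steps:

1. **Coverage**: mean GC-corrected, sample-normalised coverage in the
   ±1,000 bp window around each annotated TSS, aggregated from transcripts
   to genes by the arithmetic mean.
2. **Correlation**: for every cell type in an averaged single-cell
   expression reference, Spearman's rho between that cell type's expression
   profile and the sample's per-gene TSS coverage, over the genes shared by
   both resources.
3. **Ranking**: cell types ordered by the strength of the *negative*
   correlation; the most negative rho receives the highest rank `N`.
   Higher rank means greater inferred contribution to the cfDNA pool.

The method yields per-sample relative ranks, not absolute proportions; all
cohort statistics downstream operate on ranks.

## Coverage model and numerical choices

A fragment contributes its weight at every base it overlaps inside the
window (a pileup, not a midpoint count). The per-transcript value is the
summed weighted depth divided by the full window length (2·1,000 + 1),
then by the sample-wide mean over all annotated windows, so each sample's
coverage averages exactly 1. Ranks are invariant to any per-sample
monotone rescaling, so this normalisation only fixes a convenient scale.
Windows that would extend below position 0 are clipped (with a warning)
but still divided by the full window length. A window with no overlapping
fragments scores 0 — a genuine observation of absent coverage, not a
missing value; externally loaded coverage tables may still contain `NA`s,
which the correlation step drops pairwise per cell type.

**GC correction.** Fragments are binned by GC fraction into 50 equal-width
bins on [0, 1]; each bin is weighted by `global mean rate / bin rate`, and
weights are rescaled so their fragment-weighted mean is exactly 1. When
the GC composition of the annotated windows is available, a bin's rate is
fragments *per window* in that GC stratum (observed over expected). This
matters: with raw counts, the uneven number of windows per GC stratum
leaks into the weights and re-injects noise correlated across genes of
similar GC. The contract is deliberately minimal — corrected coverage must
be decorrelated from GC content — and is verified in a null simulation
where coverage depends only on GC (|Spearman| drops from > 0.3 to < 0.05
at 2,000 genes). Fragments lacking GC values fall back to an identity
model with a warning.

**Ties and missingness.** Spearman uses average ranks (tie-aware) on both
sides; cell types whose ranked vectors have zero variance, or with fewer
than 3 complete gene pairs, get a missing rho and are excluded from
ranking, reducing `N` for that sample with a warning. Tied rho values
receive average ranks.

## The synthetic-data generator

No raw patient data accompany the analyses this package implements, so the
generator is first-class, tested code that defines the study conditions.
It emulates the statistical structure the deconvolution assumes:

* **Reference**: `K` cell types over `G` genes; each type has a disjoint
  block of marker genes with lognormal expression (location
  `log(expr_scale)`, scale 0.5) and *zero* background, so the
  mixture-weighted bulk profile has a genuine TPM = 0 (unexpressed) class.
  Types cycle through the eight blood-relevant categories (monocytes,
  lymphocytes, granulocytes, progenitor/erythroid, endothelial, other
  tissue, stromal, hepatic) and through a tissue list, mirroring the
  one-row-per-tissue convention of multi-tissue atlases.
* **Coverage**: `cov_g = B · g(GC_g) · (1 − d·s_g) · ε_g` with
  `s_g = log1p(x_g)/max log1p(x)` for mixture-weighted expression `x`,
  `g(GC) = 1 + a·(GC_g − mean GC)`, and lognormal noise `ε`. The log1p
  transform is one monotone, bounded choice among many; rank-based
  inference downstream only needs monotonicity.
* **Fragments**: candidate midpoints uniform over the window plus a
  fragment-length margin; a midpoint at offset `u` survives with
  probability `1 − d·s_g·exp(−u²/(2·300²))`, a Gaussian
  nucleosome-depletion kernel whose 300 bp scale matches the qualitative
  width of observed TSS dips. Fragment lengths are normal (167 ± 20 bp,
  truncated at 50); per-fragment GC is the gene's window GC plus small
  jitter, and genes receive candidates proportional to `g(GC)·ε`, so the
  GC correction is genuinely exercised. The window-averaged expectation of
  this process is `∝ 1 − d·s·κ` with `κ` the length-smeared kernel mean;
  `expected_fragment_coverage()` computes it numerically and the test
  suite verifies 5% agreement at 10^5 fragments.
* **Cohorts**: healthy mixture weights are Dirichlet draws (concentration
  100) around a hematopoietic base (monocytes 0.30, lymphocytes 0.25,
  granulocytes 0.20, the rest split evenly), reflecting the known
  dominance of myeloid and lymphoid turnover in plasma. Cancer samples
  move `Δ` of weight from the monocyte to the lymphocyte category before
  drawing — the adaptive-up/innate-down pattern reported for cancer
  cohorts. Longitudinal designs add per-timepoint category offsets, and
  relapse patients an extra post-baseline lymphocyte offset. Each sample
  has its own RNG stream derived from `(seed, sample_id)`, so cohorts are
  reproducible regardless of generation order. The exact weights used are
  recorded as ground truth.

No quantitative effect size for the lymphocyte/monocyte shift is available
from real data, so `Δ` defaults are chosen for testability (0.15–0.2),
not biological calibration. The generator also does not attempt
dinucleosome fragment-length structure, sequence-level simulation, or
tumor-mutation spike-ins; passing tests therefore demonstrate correctness
of the inference machinery under the stated model, not performance on real
plasma.

## Cohort statistics

Group contrasts use two-sided Wilcoxon rank-sum tests (exact when the
smaller arm has ≤ 8 observations and there are no ties, otherwise the
normal approximation with tie and continuity corrections; fully tied
samples give p = 1), fold changes of median ranks
(`log2(median_case/median_control)`), and Benjamini–Hochberg adjustment
with one FDR family per contrast call. Longitudinal comparisons test each
timepoint against baseline *unpaired*, matching the descriptive convention
of treatment-timeline figures even though samples are paired; a paired
signed-rank variant sits behind `paired = TRUE` for sensitivity analyses.
For volcano views, a cell type observed in several tissues keeps only the
instance with the largest |log2 FC| (read as absolute, since a volcano
displays both directions), with ties broken by smaller q then tissue name.
Rank-change features use type-7 (linear interpolation) quantiles for the
IQR, the R default.

A structural caution discovered while validating: the fold change of
*median category ranks* is only informative when categories have several
member cell types. With one type per category the top category saturates
at rank `K` in both arms and its log2 FC degenerates to 0 despite a real
shift. Cohort-level studies in this package therefore use K = 24 (three
types per category); the real feature space of the motivating analyses has
~170 immune cell types, so this is the faithful direction to scale.

## Classifier and survival

`fit_lasso_logistic()` minimises mean negative log-likelihood plus
`λ·Σ|β|` (intercept unpenalised) by penalised IRLS with cyclic coordinate
descent, converging when the largest coefficient change falls below 1e-7.
Predictors are standardised to mean 0 / population variance 1, under which
`λ ≥ max|xᵀ(y − ȳ)|/n` yields exactly the all-zero model, and
Karush–Kuhn–Tucker conditions are checkable to 1e-6 (`lasso_kkt()`).
`loocv_predict()` evaluates the 100-value log-spaced grid on
[1e-4, 1e1]: each sample is held out, the training fold standardised on
its own statistics (no leakage), the full path fitted with warm starts,
and the held-out probability recorded; the λ maximising out-of-fold AUC is
chosen (ties to the larger, sparser λ) and reported with its LOOCV AUC and
a DeLong confidence interval. Using the same LOOCV for tuning and
reporting reproduces the conventional single-level procedure of
caret-style analyses and carries its optimistic bias, documented here
rather than hidden.

A second, opposite bias deserves note: pooled LOOCV probabilities are
*pessimistic* under the null, because removing a case lowers the training
class balance and the unpenalised intercept then anti-orders every
held-out sample. When the feature count is small relative to n, even the
best λ on the grid can sit visibly below AUC 0.5 on null data (we measure
0.26–0.59 across replicate null cohorts at p = 9, n = 60). The bias
dilutes as p grows toward and beyond n — the regime of the motivating
analyses — and does not affect the signal case.

Detection calls choose the smallest control-score threshold leaving at
most `1 − specificity` of controls at or above it (95% specificity by
default). Survival stratification splits at the median predicted
probability (exact median goes to "low", deterministically);
recurrence-free survival is administratively censored at 36 months, then
Kaplan–Meier curves (via the survival package's product-limit estimator)
and a log-rank test compare the strata. Time zero is the baseline/surgery
date supplied in the sample sheet.

## Problem sizes used in validation

The shipped validation suite runs, per study: Table-1-style summaries on
the printed cohort counts; TSS-depletion validation at G = 1,000 genes and
10^5 fragments (d = 0.8 and d = 0); exact one-hot recovery plus 100 noisy
samples (σ = 0.1, K = 8) for top-2 rank recovery; a GC-only null at
G = 2,000 and 4·10^5 fragments; kernel-vs-oracle checks on ≥ 100 random
instances each (tolerance 1e-12; 1e-6 for the iterative fit's KKT);
125 null cohorts (8 category features each, 20 vs 20) for type-I error and
50 replicate shifted cohorts (Δ = 0.2, 30 vs 30) for power; classifier
checks at n = 40 with 20 permutation replicates; and one full
fragment-level case–control design (30 vs 30, Δ = 0.15, σ = 0.15,
2·10^4 fragments/sample, K = 24). These sizes are the package's chosen
study conditions; `scripts/acceptance.R` re-runs them from scratch for any
seed.

## Known limitations

* Ranks are relative: a rise in one category forces falls elsewhere, and
  rank features within a sample are negatively correlated by construction.
* cfDNA reflects cell *turnover*, not circulating counts; the generator
  models mixture weights directly and is silent on that distinction.
* The unpaired longitudinal default ignores within-patient pairing.
* The single-level LOOCV reports an optimistically tuned AUC and a
  pessimistic null, as described above.
* The GC model corrects composition bias at fragment resolution only; it
  does not reproduce a full genome-context correction (mappability,
  k-mer effects), which the coverage contract does not require.
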