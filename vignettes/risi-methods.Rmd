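---
title: "Scoring the resistance / systemic-inflammation balance: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the resistance / systemic-inflammation balance: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(risibalance)
```

## The model

Infection triggers two distinct transcriptional programs in circulating
immune cells: a *resistance* program (R) tied to the detection and
elimination of the pathogen, and a *systemic inflammation* program (SI).
Both are described by predefined per-gene weight vectors derived in earlier
experimental systems and treated here strictly as inputs; this package never
re-derives them. Each program comes paired with a confounder program (T for
R, IM1 for SI) whose weights must be co-fitted so that shared structure is
not misattributed.

For sample $i$ with preprocessed expression profile $Z_i$ over the genes
shared with a weight map, the level of each program pair is estimated by
ordinary least squares:

$$Z_i = b_i + s_{T,i} V_T + s_{R,i} V_R \qquad
  Z_i = b_i + s_{IM1,i} V_{IM1} + s_{SI,i} V_{SI}$$

fitted as two separate two-predictor regressions — matching how the pairs
were defined, and keeping each pair's estimate interpretable even when the
other pair's genes are poorly measured. The coefficients $s_{R,i}$ and
$s_{SI,i}$ are the sample's R and SI levels. Because the two raw levels live
on different scales, both are standardized against the healthy controls of
the cohort (mean/SD of the controls' levels), and the **R/SI-balance score**
is the difference $z_R - z_{SI}$. Positive balance (R above SI) typifies
moderate infection; negative balance ("impaired") typifies sepsis. Patients
with sepsis are stratified into three endotypes: *moderate imbalance*
(balance at or above a threshold), and among the rest, *high SI* (SI level
in the cohort's upper tail) versus *severe imbalance*.

## Preprocessing

Every bulk matrix passes a four-step pipeline before inference:

1. **Missing policy.** On linear (FPKM-like) data, zeros are treated as
   missing. The regime depends on the overall missing fraction $m$:
   $m<1\%$ drops any gene with a missing value; $1\%\le m<15\%$ drops genes
   missing in $>75\%$ of samples and imputes the rest by gene-neighbour KNN
   ($k=5$, Euclidean distance over co-observed samples normalized by their
   count); $m\ge15\%$ drops heavy genes and leaves the remaining holes
   missing — they are then excluded pairwise from each downstream fit.
2. **log2 transform** (skipped for already-log microarray input, where zeros
   are meaningful and kept).
3. **Per-sample standardization** across genes.
4. **Per-gene standardization anchored on healthy controls**: each gene is
   centred/scaled by the control mean and SD, applied to all samples, so
   patient values are expressed as deviations from the healthy state.

All standard deviations are population SDs (divide by $n$). The convention
is unstated in the original description of the procedure; the population
form makes the pipeline's invariants exact (post-step-3 samples have mean 0,
SD 1 exactly) and is applied consistently everywhere, including level
standardization. Step 3 has a consequence worth knowing: each sample is
divided by its *own* transcriptional dispersion, which grows with the
sample's total latent activity. Extreme states are therefore mildly
compressed, and even noise-free synthetic data are recovered at $r \approx
0.95$, not $r = 1$ — the residual is a property of the prescribed
normalization, not estimation error.

## Validation of the programs

Two complementary schemes ask whether the predefined weights actually
explain blood transcriptomes.

**Hold-out explained variance.** Genes are partitioned into 10 disjoint
folds. For each fold, R and SI levels are re-inferred from the *other* 90%
of genes; each held-out gene is then regressed on the inferred levels under
three models (joint, R-only, SI-only), recording $R^2$ and the regression
p. A matched permutation run shuffles the sample labels of the level
vectors (identity permutation excluded) to give a null $R^2$ distribution;
empirical p-values use the +1-corrected estimator
$(1 + \#\{null \ge real\})/(1 + N)$, so they are never exactly zero. The
fraction of genes with $R^2 > c$ in real and permuted data give TPR and FPR
per cutoff; precision is computed under the matched equal-size convention
$\mathrm{TPR}/(\mathrm{TPR}+\mathrm{FPR})$, and F1 is the harmonic mean
(defined as 0 when both rates vanish). The "10 repeats of 10% without
replacement" scheme is read as one partition into 10 disjoint folds — the
without-replacement clause forces disjointness.

**Inter-gene variation.** Per sample, the profile is regressed on the
weight columns themselves; the null permutes the weight rows jointly across
genes (200 permutations by default). Permutation counts (100 gene-level,
200 sample-level) are this package's defaults, chosen for p-resolution at
interactive runtimes; both are arguments.

## Benchmarking candidate programs

Candidate programs — unweighted genesets or weighted maps — are scored by
(1) a disease-response statistic: the two-sample Mann–Whitney rank statistic
standardized to a z score, signed positive for upregulation in disease (an
unpaired comparison, so the two-sample member of the Wilcoxon family is the
applicable one), and (2) cross-dataset covariation. The original covariation
ranking came from a remote co-expression retrieval engine over hundreds of
blood datasets; that service is not reproducible offline, so the package
substitutes a local statistic — mean pairwise correlation among program
genes, z-scored against size-matched random genesets per dataset — and keeps
the downstream F1 layer agnostic: externally produced rankings are accepted
verbatim. The covariation-F1 score averages F1 over cutoffs placed at each
positive dataset's rank. Note a subtlety of this definition: even a perfect
ranking scores below 1, because the lowest cutoffs pay a recall penalty
(two positives ranked 1–2 of any list score $\tfrac12(\tfrac23 + 1) = 5/6$).
Weighted programs used as covariation queries are converted to their 100
top-weight genes.

## Single-cell responses

Cells are normalized to counts-per-10k (dropout zeros kept — zeros are data
in droplet counts), log2(1+x)-transformed, standardized per cell, and scored
with the same per-sample regression. The patient's *R (or SI) response* in a
cell subpopulation is the Welch t statistic's p-value comparing the
patient's cells against all pooled control cells of that subpopulation,
reported as $-\log_{10} p$ signed by direction. Welch's form is used because
per-patient cell counts and variances differ grossly; p-values are floored
at $10^{-300}$, capping scores at 300. Per-cell preprocessing omits the
missing-value policy and the control-gene standardization of the bulk
pipeline: both would be distorted by dropout structure.

## Associations, markers, enrichment

Variance in a phenotype (protein, clinical score) explained by SI, R, or
their linear combination is the OLS $R^2$, with an empirical p from
permuting the phenotype (1000 by default). The joint model always dominates
the single models (nested OLS), which the tests assert as an invariant.
Balance markers are genes ranked by their mean per-cohort Pearson
correlation with the balance score (unweighted mean across cohorts;
Pearson is used throughout for consistency), selected at $>0.6$ (good) or
$<-0.45$ (impaired), with the top 300 per direction chosen by the monocyte
cohort's correlations. Enrichment of marker sets against GMT collections is
an upper-tail hypergeometric test with Benjamini–Hochberg q-values.

## Survival

Endotype prognosis is evaluated with Kaplan–Meier curves, the log-rank test
(or the generalized-Wilcoxon/Breslow weighting), and Cox proportional
hazards with age and sex as covariates and Efron tie handling — daily
resolution makes ties common. Follow-up is administratively restricted to
28 days. The endotype thresholds are not fixed constants of the method;
the defaults are balance ≥ 0 for moderate imbalance and the cohort's top
15% of SI for high SI, both explicit arguments, and
`calibrate_endotype_thresholds()` derives thresholds from target class
shares (e.g., the 20/62/16% mix) when calibration is preferred.

## The synthetic generator

Every stage is testable offline through `generate_cohort()` and its
companions, which encode the assumed statistical structure as ground truth:

- Per-condition latent means (R, T, SI, IM1): healthy $(0,0,0,0)$, moderate
  infection $(2, 0.5, 1, 0.3)$, sepsis $(0.5, 0.5, 2.5, 0.5)$, unit latent
  SD — sepsis has R low relative to SI, moderate infection the opposite.
- Latent covariance: unit variances with $\mathrm{cor}(R, SI) = 0.5$ within
  condition, the other pairs uncorrelated. The positive correlation reflects
  that individuals mounting a stronger response induce both programs
  together — the programs co-vary across individuals while the *balance*
  remains a condition-level trait. (Under fully independent latents the
  true balance would separate the conditions at an AUC ceiling of
  $\Phi(3/2) \approx 0.93$; the correlated default has a ceiling of
  $\Phi(3/\sqrt2) \approx 0.98$, matching the separation the score is
  designed to exhibit.)
- Genes: $\log_2$ expression = baseline $\mathcal N(6,1)$ + weights ×
  latents + $\mathcal N(0, 1)$ noise, exponentiated to linear scale so the
  zeros-to-missing, log, and standardization steps are all exercised. The
  four weight vectors are decorrelated to pairwise $|r| \le 0.1$.
- Proteins load linearly on the latents (R-loaded CXCL11/IFNg/CXCL10
  analogs, SI-loaded IL6/IL8/IL18bp/ferritin analogs, plus unloaded noise
  proteins), so the biomarker proxies run out of the box.
- Cells scatter around patient latent means (SD 0.5; patient-level SD 0.3)
  and are Poisson-thinned to ~5000 counts per cell.
- Survival: exponential times with hazard
  $\lambda\,e^{0.7\,SI - 0.7\,R}$, $\lambda$ calibrated by root-finding so
  the expected 28-day event fraction matches the 59% design target, with
  administrative censoring at day 28.

The latents are generated jointly over all four programs while inference
fits the pairs separately — deliberately reproducing the method's
model-misspecification risk; near-orthogonal weights keep the resulting
omitted-variable bias small. What the generator does *not* emulate: real
gene–gene correlation beyond the latent factors, platform/batch effects,
cell-type composition shifts, or non-exponential hazards. Passing tests
therefore demonstrate correctness of the machinery and calibration of its
permutation schemes under the assumed model, not performance on real
cohorts.

## Problem sizes and numerical choices

The test suite and the acceptance script run the default cohort at 2000
genes × 300 samples, validation nulls at 50–100 permutations, calibration
checks at 400–1500 replicates, single-cell checks at a few hundred patients
× 50–100 cells over 250–300 genes, and survival recovery at n = 500 — sizes
chosen so every property is measurable at interactive runtimes. Degenerate
inputs are errors, not silent repairs: zero-variance samples, constant
control genes (dropped with a warning), collinear weight vectors (reported
with the design's condition number), gene overlaps below 50 (the
two-predictor fit would be unstable), and fewer than 3 controls for
anchored standardization. Ranking ties keep stable input order and are
flagged. When a cohort has no healthy controls, level standardization falls
back to the cohort itself and the output carries an explicit
`reference_mode = "cohort"` flag — the only self-contained option.

## Reproducibility

Every stochastic routine takes an explicit seed; the pipeline flows one
root seed through fixed per-stage offsets, and two runs with identical
inputs produce bit-identical outputs (asserted on file checksums in the
manifest). Homolog transfer between species uses strict one-to-one maps;
gene identifiers are opaque case-sensitive strings, and probe collapsing is
the caller's responsibility.
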