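# risibalance

Scoring of two transcriptional programs of the host response to infection —
**resistance (R)**, the immune activation tied to detecting and eliminating
the pathogen, and **systemic inflammation (SI)** — and of the **R/SI-balance
score** that separates sepsis from moderate infection. Patients with sepsis
share a fingerprint of low R relative to SI; the diversity of R and SI
states beneath that fingerprint (high SI, low R, or both) stratifies
patients into prognostic endotypes. The package is aimed at computational
immunologists analysing bulk or single-cell blood transcriptomes, plasma
proteomics, and clinical outcome data of infection cohorts.

## The model

R and SI levels are inferred per sample from *predefined* gene-weight maps
(external inputs; each program ships with a confounder program — T for R,
IM1 for SI — that must be co-fitted). For sample *i* with preprocessed
expression profile *Z<sub>i</sub>*, two separate ordinary-least-squares
fits

> *Z<sub>i</sub>* = *b<sub>i</sub>* + *s<sub>T,i</sub>* **V**<sub>T</sub> + *s<sub>R,i</sub>* **V**<sub>R</sub>  
> *Z<sub>i</sub>* = *b<sub>i</sub>* + *s<sub>IM1,i</sub>* **V**<sub>IM1</sub> + *s<sub>SI,i</sub>* **V**<sub>SI</sub>

yield the raw levels *s<sub>R,i</sub>* and *s<sub>SI,i</sub>*. Both are
standardized against healthy controls, and the balance score is
*z<sub>R</sub>* − *z<sub>SI</sub>*: positive = R above SI ("good" balance,
moderate infection), negative = "impaired" balance (sepsis).

Around this core the package provides: the four-step preprocessing pipeline
(missing policy with KNN imputation, log2, per-sample standardization,
control-anchored gene standardization); hold-out and permutation
explained-variance validation of the programs with TPR/FPR/F1 summaries;
program benchmarking by disease response (signed rank z) and cross-dataset
covariation F1; per-cell scoring with patient-level signed log10-p response
statistics; phenotype/protein association (permutation-tested variance
explained, 2D correlation maps, balance-marker ranking, hypergeometric
enrichment); endotype assignment with Kaplan–Meier/log-rank and Cox
survival analysis; and a synthetic-cohort generator with retrievable ground
truth for all of the above.

## Worked example

A fully synthetic cohort (1000 genes; 50 healthy, 40 moderate infection,
40 sepsis) scored end to end:

```r
library(risibalance)

cfg <- generator_config(n_genes = 1000,
                        n_per_condition = c(healthy = 50,
                                            moderate_infection = 40,
                                            sepsis = 40),
                        seed = 42L)
co   <- generate_cohort(cfg)
ctrl <- co$bundle$samples$sample_id[co$bundle$samples$condition == "healthy"]
z    <- preprocess_pipeline(co$bundle$expression, control_sample_ids = ctrl)
lev  <- standardize_levels(program_levels(z, co$w_rt, co$w_si), ctrl)
head(lev[, c("sample_id", "s_R", "s_SI", "z_R", "z_SI", "balance")], 3)
#>     sample_id          s_R       s_SI         z_R       z_SI   balance
#> 1 healthy_001  0.007577962 -0.5023499  0.02057234 -1.2268533  1.247426
#> 2 healthy_002 -0.674829883 -0.3030206 -1.83200070 -0.7400457 -1.091955
#> 3 healthy_003 -0.116029407 -0.8460396 -0.31499191 -2.0662222  1.751230
```

The balance score separates the conditions in the expected direction —
median balance −0.12 in healthy, **+1.15** in moderate infection,
**−1.64** in sepsis — and ranks sepsis below moderate infection with
AUC 0.976:

```r
cond <- co$bundle$samples$condition[match(lev$sample_id,
                                          co$bundle$samples$sample_id)]
keep <- cond != "healthy"
rank_auc(-lev$balance[keep], cond[keep] == "sepsis")
#> [1] 0.975625
```

Sepsis patients are stratified into the three endotypes (thresholds
calibrated to the 20/62/16% class mix):

```r
sep  <- lev[cond == "sepsis", ]
th   <- calibrate_endotype_thresholds(sep)
endo <- assign_endotypes(sep, th$balance_thresh, th$si_quantile)
table(endo$endotype)
#>            high_SI moderate_imbalance   severe_imbalance
#>                  5                  8                 27
```

Survival analysis of the endotypes (`km_logrank()`, `cox_ph()`) needs more
patients than this toy cohort provides; `scripts/acceptance.R` runs it at
n = 500, where the Cox model recovers the generator's log-hazard
coefficients (+0.7 on SI, −0.7 on R) to well within their standard errors.
The per-gene validity checks (`heldout_variance()`,
`permuted_null_heldout()`, `percent_significant()`) and the single-cell
response statistics (`per_cell_levels()`, `patient_response()`) follow the
same pattern; see the methods vignette (`vignettes/risi-methods.Rmd`) for
the full account of the model, defaults, and limitations.

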