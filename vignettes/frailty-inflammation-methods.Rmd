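---
title: "Methods: deficit-accumulation frailty and inflammation association pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deficit-accumulation frailty and inflammation association pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailomics)
```

## The model

### Deficit-accumulation frailty index

A frailty index (FI) summarises a person's accumulated burden of health
deficits — symptoms, diseases, disabilities, functional limitations — as a
single proportion. Each deficit $j$ is coded $x_{ij} \in [0, 1]$ for subject
$i$: binary deficits as 0 (absent) / 1 (present), graded deficits at
intermediate values (e.g. 0 / 0.5 / 1 for none / some / severe limitation).
The index is

$$\mathrm{FI}_i = \frac{\sum_{j \in M_i} x_{ij}}{|M_i|},$$

where $M_i$ is the set of deficits *measured* for subject $i$. The
denominator is the count of measured deficits, not the schema size: a
subject with one unmeasured deficit in a 38-deficit index is scored over 37.
This renormalisation is what makes the index robust to scattered
missingness, and it is asserted exactly in the tests. Scores lie in
$[0, 1]$; subjects at or above a cutoff (default 0.25, inclusive) are
labelled frail.

Construction is schema-driven. A `deficit_schema` document declares each
deficit's name, category (one of six: self-reported disease, general daily
function, physical function and activity, self-reported health, mood, and
cognitive function), source column, and coding map. The packaged
`deficit_schema_38.json` is a **replica** schema: 38 deficits across those
six categories with explicit, assumed grading maps. The exact deficit list
and gradings of any particular cohort belong in the schema file, which users
edit; nothing about the index definition lives in code. Standard practice
requires at least 30–40 deficits for a stable index, so `load_schema()`
warns (but does not fail) below 30.

Two screening rules are applied before scoring:

* **deficit-level**: a deficit missing in $\ge$ 20% of subjects is excluded
  (the comparison is inclusive at the threshold);
* **subject-level**: a subject with fewer than 80% of deficits measured is
  flagged `excluded` and omitted from downstream stages (configurable).

Two further criteria for a valid deficit — it should generally increase with
age, and it should not saturate early in the age range — are reported by
`screen_deficits()` as advisory diagnostics (Spearman correlation with age;
prevalence above 0.95 flagged as saturated) and never exclude a deficit
automatically, because these judgements are substantive, not mechanical.

### Biomarker associations

Six circulating inflammation-related markers are handled: IL-6 (pg/ml), CRP
(mg/L), IGF-1 (ng/ml), cystatin C (ng/ml), cathepsin S (pg/ml), and
glycoprotein acetyls (mmol/L). The transform policy natural-log transforms
the right-skewed markers (CRP, IL-6, cystatin C) and excludes CRP values
$\ge$ 50 mg/L from CRP analyses only — values that high indicate acute
infection, not the chronic low-grade inflammation of interest. Non-positive
values under the log are set missing with a logged count rather than raising
an error, since they signal an assay floor.

Three analysis layers:

* **Spearman correlation** of FI with each marker, overall and per stratum
  (e.g. sex), on pairwise-complete observations. Rank correlation is
  invariant to the log transform, so the transform matters only for the
  model-based layers.
* **Group comparisons** (frail vs non-frail, women vs men) with automatic
  test selection: continuous variables use the t-test when Shapiro–Wilk
  accepts normality at $\alpha = 0.05$ in both groups and the Mann–Whitney U
  test otherwise; categorical variables use the Pearson chi-square test,
  switching to Fisher's exact test when any expected cell count is below 5
  (the classical rule). All tests are two-sided. Summary formats follow the
  same normality rule: mean ± SD, median (min–max), or n (%).
* **Adjusted linear models** with the FI score as the dependent variable,
  one marker at a time as exposure, adjusted for age, sex, BMI and smoking,
  on listwise-complete rows (so n varies by marker, and is always
  reported). For ln-scale markers the coefficient and CI are additionally
  multiplied by $\ln(1.1)$ and reported as the change in FI per 10%
  increase in the marker. The identity behind this back-transform —
  $\beta\ln(1.1)$ equals the model-predicted FI difference between marker
  levels $m$ and $1.1m$, for any $m > 0$ — is asserted to $10^{-12}$ in the
  tests.

The natural log (not log10) is required for this reading of the
back-transform and is used throughout. Sex enters regressions as a binary
indicator with male as the reference level.

### Transcriptome stage

Bulk PBMC expression arrives as a probes × samples matrix of log2
intensities (background correction is assumed done upstream). Preprocessing:

* **Quantile normalisation** forces every sample onto the common reference
  distribution of rank means; tied entries receive the mean of the
  corresponding reference quantiles (delegated to
  `limma::normalizeQuantiles`, ties averaged).
* **Probe collapse** keeps, per gene, the probe with the largest IQR across
  samples — the most informative probe — with IQR ties broken by the
  lexicographically smallest probe id so results are deterministic.

**Per-gene models.** For each gene, expression is the response and the FI
score the main exposure (so a positive coefficient means higher expression
with increasing frailty), adjusted for age and BMI by default; crude and
cell-proportion-adjusted variants are available. All genes share one design
matrix, so the fits are computed with a single Cholesky factorisation and
cross-checked in the tests against a literal `lm()` loop. P-values are
two-sided; tier counts at 0.05 / 0.01 / 0.001 and Benjamini–Hochberg
q-values (Bonferroni via config) summarise the multiplicity. The expression
subgroup in the motivating design is single-sex, so sex is not in the
default transcriptome adjustment set.

**Deconvolution.** Cell-type proportions are estimated per sample by
nonnegative least squares of the *linear-scale* expression ($2^{\log_2}$)
on a signature matrix (signature genes × cell types, linear scale), with
the coefficients renormalised to proportions summing to one — in-silico
flow cytometry with relative proportions. Constrained least squares is used
deliberately instead of a support-vector formulation: it is transparent,
fast, and exactly testable against a brute-force simplex enumeration. In
the tests the enumeration oracle searches the simplex with a free positive
scale factor, which is the exact combinatorial counterpart of
NNLS-plus-renormalisation. Noiseless mixtures are recovered to $10^{-9}$.
The signature matrix is fully pluggable, so an LM22-style reference can be
substituted.

**Monocyte markers.** Genes are ranked by the significance of their
Spearman correlation (Pearson via config) with the deconvolved monocyte
fraction; the top 30 are retained. Each (gene, biomarker) pair is then
z-scored and the standardized gene expression regressed on the standardized
biomarker with age and BMI as covariates; the coefficient matrix carries
significance stars at 0.05/0.01/0.001 and row/column orders from
hierarchical clustering (Euclidean distance) for heatmap display.

## The synthetic cohort generator

Because cohort phenotype data of this kind are rarely public, the package
ships a generator whose defaults *are* the study conditions the analyses
assume, with a ground-truth object for recovery testing:

* **Cohort** (n = 400): age 70 + Exponential(median 4 years) truncated at
  93 (median near 74); 52% women; BMI $\mathcal{N}(26.2, 3.9^2)$; 6% daily
  smokers; living alone more likely at higher frailty.
* **Latent frailty**: Beta-distributed with mean $0.127 + 0.004(\text{age} -
  70)$ and concentration 30. The base mean was set analytically so the
  population mean FI lands near 0.15. The latent construct is purely a test
  harness — no claim is made that real frailty has a one-dimensional latent
  cause.
* **Deficits**: for each deficit the coded levels are ordered by severity
  and an index drawn as Binomial($k-1$, $p$), with $p$ a logistic-steepness
  transform of latent frailty (steepness 1 is the identity), so the
  expected FI equals the expected latent value by construction.
  Missingness is injected completely at random at rate 0.02; informative
  missingness is out of scope.
* **Biomarkers**: $\ln(\text{marker}) = \alpha + \beta \cdot
  \text{latent} + \varepsilon$. Intercepts put medians near typical
  elderly-cohort values (IL-6 ~1.4 pg/ml, CRP ~1.5 mg/L, IGF-1 ~86 ng/ml,
  cystatin C ~780 ng/ml, cathepsin S ~8000 pg/ml, Gp-acetyls ~1.26 mmol/L);
  slopes and noise SDs are set so Spearman correlations with the FI land in
  the 0.15–0.3 range seen for inflammatory markers in elderly cohorts.
  IGF-1 carries a negative slope. These are cosmetic calibrations for
  realism, not claims.
* **Expression** (default 89 samples, women only; 5,000 genes): per-sample
  proportions over five cell types with the monocyte fraction $0.20 + 0.25
  \cdot \mathrm{FI} + \mathcal{N}(0, 0.03^2)$, clipped to [0.01, 0.90] and
  the remainder split by a Dirichlet draw around the other baselines; a
  log-normal signature matrix in which 50 planted genes are strongly
  monocyte-specific (signature 500 in monocytes vs 5 elsewhere); bulk =
  signature × proportions with multiplicative log-normal noise (SD 0.05),
  returned on the log2 scale.

**The recovery harness.** `simulate_biomarkers()` generates markers *from*
latent frailty, so the implied coefficient of the reverse regression
(FI on ln marker) is not one of its parameters. Calibration and coverage
experiments therefore use `simulate_regression_truth()`, which draws the
FI score directly from the model that `adjusted_linear_model()` fits; there
the coefficient is the exact estimand. Scores are deliberately not clamped
to $[0,1]$ in that harness, since truncation would bias the estimand; with
the default effect sizes they essentially never leave the interval.

**What the generator does not emulate.** Microarray noise physics, batch
and array effects, informative missingness, sex differences in expression,
correlated deficits beyond the shared latent, and medication effects are
all absent. Passing recovery tests therefore demonstrates that the
pipeline's estimators are correct and calibrated under clean conditions —
not that the same effect sizes would be estimable in any particular real
cohort. One visible consequence: because every simulated gene's bulk
expression moves with cell proportions, and proportions track the FI, the
per-gene stage finds far more nominally significant genes on synthetic data
than a real cohort of this size typically shows.

## Numerical and design choices

* Missingness exclusion is inclusive at the threshold (a deficit missing in
  exactly 20% of subjects is dropped); the frailty cutoff is inclusive
  (FI = 0.25 is frail); CRP exclusion is inclusive (50 mg/L is excluded).
* FI scores are kept at full precision; rounding happens only in rendered
  reports (TSV outputs keep full precision, the markdown descriptive table
  rounds to 3 significant digits).
* Normality for test/format selection uses Shapiro–Wilk at $\alpha = 0.05$
  per group (subsampled at n > 5000), overridable per variable.
* The per-gene fitter refuses rank-deficient designs rather than dropping
  columns; zero-variance genes get a missing p-value and are counted.
* Probe-collapse and marker-ranking ties break lexicographically; the
  quantile-normalisation tie rule is the mean of the tied reference
  quantiles.
* Spearman p-values use the asymptotic approximation (`exact = FALSE`),
  adequate at the cohort sizes intended (hundreds) and consistent across
  tied and untied data.
* Problem sizes in the test suite (e.g. 10,000-gene null panels at 89
  samples, 200-replicate calibration runs at n = 400, 1,000-matrix
  brute-force comparisons) were chosen as the smallest scales at which the
  statistical assertions are sharp.

## Known limitations

* The replica schema's gradings are assumptions; any substantive use
  requires substituting the cohort's real deficit definitions.
* Constrained least squares deconvolution, unlike ν-SVR approaches, has no
  feature-selection step and is sensitive to signature genes that are
  poorly measured; the signature should be restricted to reliable marker
  genes.
* The group-comparison normality gate is itself a test; with very large
  groups Shapiro–Wilk rejects trivial departures and routes nearly
  everything to the Mann–Whitney U test. This is conservative, not wrong.
* The pipeline is cross-sectional by design: no longitudinal FI
  trajectories, no outcome validation (mortality, hospitalisation), no
  causal or mediation analysis.
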