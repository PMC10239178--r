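---
title: "Smoking, epigenetic age acceleration, and health outcomes: the mediation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smoking, epigenetic age acceleration, and health outcomes: the mediation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eaamediate)
```

## The scientific question

Cigarette smoking damages glycaemic control and ventilatory lung function,
and it also leaves a broad footprint on blood DNA methylation. Several
composite DNAm biomarkers of aging - epigenetic age acceleration (EAA)
measures such as Hannum EAA, intrinsic EAA (IEAA), PhenoAge EAA, GrimAge
EAA, the GrimAge components DNAm-predicted smoking pack-years and DNAm
PAI-1 levels, and the pace-of-aging estimator DunedinPACE - respond to
smoking and predict morbidity. `eaamediate` asks, and answers with a
reusable tested pipeline, to what extent these biomarkers *mediate* the
association between smoking and four health outcomes: fasting glucose (FG,
mg/dL), HbA1c (%), FEV1 (L), and FVC (L).

## The model

Every analysis cell pairs two ordinary least-squares regressions fit on
one shared analysis sample. For smoking status (former `FS` and current
`CS` dummies, non-smokers as the reference group):

$$M = \beta_{0M} + \beta_{X_1M}\,FS + \beta_{X_2M}\,CS +
      \boldsymbol\beta_{CM}'\mathbf{C} + \varepsilon_M$$
$$Y = \beta_{0Y} + \beta_{X_1Y}\,FS + \beta_{X_2Y}\,CS +
      \beta_{MY}\,M + \boldsymbol\beta_{CY}'\mathbf{C} + \varepsilon_Y$$

with $\mathbf{C}$ the adjustment set: chronological age, sex, BMI,
drinking, regular exercise, educational attainment (integer 1-7), and five
blood cell-type proportions (B, CD4+ T, CD8+ T, monocytes, NK). Analogous
pairs replace the status dummies with former/current smokers' pack-years
(`FPY`, `CPY`; non-smokers coded 0 in both), or - in former smokers only -
with years since smoking cessation (`YSC`, with pack-years added to
$\mathbf{C}$).

For each exposure term $X$ the decomposition is the classical
product-of-coefficients one:

* indirect effect (ACME): $\hat\beta_{XM}\cdot\hat\beta_{MY}$;
* direct effect (ADE): $\hat\beta_{XY}$ with the mediator in the model;
* total effect: their sum;
* proportion mediated: $100\cdot\mathrm{ACME}/\mathrm{total}$, which can be
  negative or exceed 100% when the components have opposite signs.

Because both models are linear with identical covariates and sample, the
product of coefficients is algebraically identical to the
difference-of-coefficients estimator (the exposure coefficient without
minus with the mediator); the test suite checks this identity to 1e-10 on
random problems.

Inference is by nonparametric case-resampling bootstrap: rows of the
analysis sample are resampled with replacement, *both* models are refit
per replicate, and the 95% CI is the 2.5/97.5 percentile of the replicate
effects. The conventional replicate count is 2000 (`n_boot = 2000`).

## Preprocessing and its order of operations

1. **Extreme-outlier exclusion per mediator.** A value is extreme when it
   falls outside $[Q_1 - 3\,\mathrm{IQR},\ Q_3 + 3\,\mathrm{IQR}]$.
   Quartiles are estimated by linear interpolation between order
   statistics (`stats::quantile()` type 7); the `type` argument is exposed
   because the fences depend on the estimator. Fences are computed once on
   the full input cohort per mediator, before subsetting and listwise
   deletion, and treated as fixed thereafter - missing values pass through
   unflagged. Under normality the 3 x IQR fences exclude essentially
   nothing (< 0.1%); they bite only on heavy-tailed markers such as
   DNAm-predicted pack-years.
2. **Outcome transform.** FG and HbA1c are right-skewed and are
   natural-log transformed to meet the linear-model normality assumption;
   all four outcomes are then z-scored on the analysis sample. The z-score
   uses the sample SD (n - 1 denominator), the convention of mainstream
   statistical software.
3. **Listwise deletion.** Rows missing any required variable are dropped;
   there is no imputation. FEV1/FVC analyses therefore run on the
   lung-examination subsample, and each cell reports its own analysis n -
   per-mediator outlier counts make the n differ across cells exactly as
   in per-cell "sample size" columns of published mediation tables.

Fences and z-scores are *not* recomputed inside bootstrap replicates: they
are fixed preprocessing, performed before mediation analysis. Consequently
point estimates are invariant to the bootstrap seed; only CIs and p-values
depend on it.

## Screen, grid, and multiplicity

The mediation grid is guarded by a Bonferroni screen: each of the seven
markers is regressed on the smoking variables (models for status,
pack-years, and cessation), and associations with
$p < \alpha/(7 \times 5) = 0.0014$ count as real. A marker with *no*
surviving exposure association is not a plausible mediator and is dropped;
with the default generator this typically removes IEAA, leaving
$6 \times 5 \times 4 = 120$ mediation tests. All 120 bootstrap p-values
form a single family for Benjamini-Hochberg FDR control at 0.05. Two
deliberate choices:

* the screen's p-values are *not* part of the FDR family - the two stages
  use distinct corrections;
* per-exposure FDR grouping is available (`fdr_family = "exposure"`),
  since published reports sometimes adjust within table blocks, but the
  single family is the default because the 120 p-values are described as
  one family.

Exposure terms sharing a model pair (FS/CS; FPY/CPY) are read from the
same joint fits, and one set of bootstrap refits serves both exposures.

## The synthetic-cohort generator

Individual-level cohort data of this kind are access-restricted, so the
package ships a generator whose defaults emulate the reference cohort of
2474 Taiwanese adults aged 30-70:

* group prevalences 0.7595 / 0.1261 / 0.1144 (non / former / current);
* male shares 39.2% / 87.2% / 83.0%; drinking 3.8% / 9.6% / 24.4%;
  regular exercise 43.6% / 57.1% / 33.6%; BMI 24.1 +/- 3.7, 25.3 +/- 3.2,
  25.4 +/- 3.7 kg/m2; education 5.6 +/- 0.9, 5.6 +/- 0.9, 5.4 +/- 0.8;
* former smokers' pack-years 12.9 +/- 14.1, current smokers' 20.8 +/-
  19.9, years since cessation 12.9 +/- 10.0;
* exposure-to-mediator coefficients at the observed scale (e.g. current
  smoking raises GrimAge EAA by 5.650 years, DNAm pack-years by 14.916);
* 36.3% of participants jointly missing FEV1/FVC (skipped lung exam);
* FG/HbA1c generated linearly on the log scale and exponentiated, so the
  pipeline's log transform exactly linearises the outcome model and the
  marginals are right-skewed.

Free parameters the printed record does not pin down are package choices,
stated once and not revisited:

* **Mediator residual SDs** are back-calculated from the reported
  coefficient standard errors at n = 2474 (e.g. a CS standard error of
  0.201 for GrimAge EAA implies a residual SD near 3.2 years).
* **Mediator-to-outcome coefficients** are set so that second-generation
  aging markers push glycaemic outcomes up and lung volumes down at
  magnitudes that give Table-scale indirect effects; they are fully
  configurable per outcome.
* **Pack-years / years-since-cessation distributions.** Only the mean and
  SD are reported. A Gaussian truncated at zero would *not* reproduce
  those two moments (truncating N(12.9, 14.1) at zero inflates the mean to
  about 17.4), so the generator uses gamma distributions with shape and
  rate solved from the configured mean and SD: nonnegative, right-skewed,
  and exactly moment-matched.
* **Joint covariate structure** is unspecified; covariates are drawn
  independently within smoking group, the simplest structure that
  reproduces the group-level confounding the models adjust for.
* **Cell proportions** are a six-part Dirichlet (granulocyte remainder
  implicit); five parts are emitted, each nonnegative with sum at most 1.
* **Age** is uniform on 30-70 in every group; group differences in age are
  deliberately not simulated, so age acts as an adjustment variable rather
  than a confounder in synthetic data.

The generator's structural equations include all five exposure terms
jointly. The fitted model pairs are *reduced forms* of that structure:
under the default truth a status-model CS coefficient also absorbs the
dose effect accumulated through current smokers' pack-years. `truth_acme()`
returns the structural product, which equals the pipeline estimand only
when the complementary exposure coefficients are zero - recovery and
coverage tests therefore use status-only truths, which is also the
configuration in which a 5.650-year GrimAge effect is the generator's
ground truth.

What passing tests on these cohorts do *not* show: robustness to
covariate-dependent missingness, to nonlinear dose-response, to
measurement error in self-reported smoking, or to residual confounding -
none of which the generator simulates.

## Numerical choices and degenerate inputs

* OLS is solved through the QR decomposition (`stats::lm.fit`), never an
  explicit inverse; an oracle test checks equality with the
  normal-equations solution to 1e-8. Rank-deficient designs raise a
  collinearity error naming the aliased columns.
* Bootstrap p-values are `2 * min(tail fractions)`, floored at
  `1/n_boot`; percentile CIs (not BCa) match the default of the standard
  mediation software this workflow mirrors. Replicates whose refit is rank
  deficient are dropped and counted; more than 5% failures aborts the
  cell with an instability error.
* Proportion mediated is reported as a point estimate only (no CI), and
  flagged undefined (`NA`, no exception) when `|total|` falls below a
  configurable floor (1e-12-scale by default).
* A constant mediator series leaves the 3 x IQR fences collapsed onto the
  constant, excluding nothing; an all-missing series is an error.
* Variance inflation factors are `1/(1 - R^2_j)` from regressing each
  design column on the rest (intercept included); values above 5 are
  flagged. Skewness is the unadjusted Fisher-Pearson `g1` convention.
* The exactly-zero-noise limit of the generator is *unidentifiable*: a
  noiseless mediator is an exact linear combination of the outcome-model
  design columns, so the outcome fit is rank deficient by construction.
  Deterministic recovery is instead verified with a vanishingly small
  mediator residual (1e-6), where the b-path and direct effect are exact
  and the ACME matches the generator truth to the corresponding precision.
* Kruskal-Wallis tests use the standard tie correction; chi-square tests
  of independence use no continuity correction. Both are documented
  conventions rather than externally fixed values.

## Problem sizes used by the shipped checks

The test suite exercises the estimator at sizes chosen to make the
statistical properties visible while staying lightweight: type-I error
under the complete null with 500 simulated cohorts of n = 500 at 200
bootstrap replicates (rejection at p < 0.05 stays below 7.5%; the
product-of-coefficients test is conservative under the joint null);
CI coverage of the generator ACME with 100 cohorts of n = 2000 at 500
replicates (at least 90 of 100 covered); FDR behaviour on an all-null
2 x 2 x 2 grid over 50 seeded runs. The acceptance script runs the full
seven-mediator screen and 120-cell grid on one default cohort of n = 2474
with 1000 bootstrap replicates.

## A worked cell

```{r example, eval = FALSE}
truth <- sim_truth(n = 2474, seed = 1)
cohort <- generate_cohort(truth)

fit <- run_mediation_analysis(cohort, exposure = "cs",
                              mediator = "grim_eaa", outcome = "fg",
                              n_boot = 2000, seed = 1)
tidy(fit)
glance(fit)
autoplot(fit)

grid <- run_grid(cohort, grid_spec(n_boot = 2000, seed = 1))
glance(grid)
render_tables(grid, cohort_summary(cohort), dir = "tables")
```

## Known limitations

The pipeline is cross-sectional: nothing in it establishes temporal
ordering between the biomarkers and the outcomes, and reverse causation
cannot be excluded. Single-mediator models ignore correlation among the
seven markers, so a cell's ACME partially absorbs paths through correlated
mediators - the same caveat that applies to the published single-mediator
workflow it implements. Classical OLS standard errors appear only in the
screen table; all mediation inference is bootstrap-based.
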