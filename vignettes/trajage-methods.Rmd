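---
title: "Methods: trajectory scoring, the blood-based aging clock, and counterfactual mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory scoring, the blood-based aging clock, and counterfactual mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajage)
```

`trajage` implements a complete observational-epidemiology analysis: how
life-course socioeconomic trajectories relate to biological aging measured
from blood markers, and how much of that relation flows through lifestyle,
diet, adiposity and quality of life. This vignette is the package's own
account of the methods: the models, the knobs and why they default as they
do, what the synthetic generator does and does not emulate, and the
numerical decisions a maintainer should know about.

## 1. Socioeconomic trajectory scoring

Three life stages are scored and dichotomized:

* **Childhood (around age 8).** Three 0–1 indicators: housing tenure
  (0 = rented, 1 = any dwelling ownership), access to hot water, and an
  overcrowding point (rooms/persons at or above the population median of
  0.6). Total 0–3; *low* if < 2.
* **Education.** Up to lower secondary school = *low*; upper secondary or
  post-secondary = *high*.
* **Adulthood.** A 0–6 point scale: tenure 0/1/2 (rented / one dwelling /
  more than one), occupational class 3/2/1/0 (professional-managerial /
  skilled non-manual / skilled manual / partly-skilled, unskilled or
  unclassified), and an overcrowding point (0 when rooms/persons < 1).
  *Low* if ≤ 3.

The 2×2×2 dichotomies map bijectively to eight trajectory labels anchored
at `stable_high` (high/high/high) and `stable_low` (low/low/low); the six
intermediate names describe which components drop or rise relative to the
start (e.g. high childhood + low education + low adulthood =
`education_and_material_downward`).

Two boundary conventions deserve note, since the verbal definitions leave
the equality cases open. The adult overcrowding rule is stated
directionally as "< 1 earns no point", so a ratio exactly at a cutoff earns
the favorable point at both life stages (childhood ratio 0.6 counts toward
the score). And childhood tenure, though recorded in three categories, is
coded 0–1: any ownership scores 1, because that is the only dichotomy
compatible with a 0–3 childhood total. The crowding cutoffs (0.6 and 1)
are fixed population constants by default; `score_ses(reestimate_cutoffs =
TRUE)` re-estimates them as sample medians for populations where the fixed
values are implausible.

## 2. The blood-based aging clock

The outcome is Δage = BA − CA, where BA is the prediction of a regressor
trained on circulating markers plus one-hot sex and recruitment center with
chronological age as the label.

**Quality control.** `qc_markers()` blanks values outside per-marker
plausible ranges (they are subsequently imputed — rows are never dropped,
which would silently change the analyzed sample) and removes four markers
that are near-deterministic combinations of others (total cholesterol,
plateletcrit, hematocrit, mean corpuscular hemoglobin), leaving 36
features from the 40-marker panel. The shipped ranges
(`marker_panel()`) are broad physiological bounds intended for the
synthetic panel; real analyses should review them.

**Imputation.** `impute_knn()` fills each missing cell from the k = 10
most similar rows under Gower distance: numeric columns contribute
range-normalized absolute differences, categorical columns 0/1 mismatches,
averaged over the columns observed in both rows. Numeric cells receive the
donor mean, categorical cells the donor mode (ties broken by level order;
neighbour ties broken by stable sort order). Donors must be observed on
the imputed variable; a variable with fewer than k donors, or observed
nowhere, is an error rather than a silent degradation.

**Network and training.** The regressor is a fully connected ReLU network,
default hidden widths 64–32–16 with a linear output, trained with
minibatch Adam (learning rate 1e-3, batch 32) on mean squared error for a
default of 1000 epochs, on a seeded random 80% of the sample.
Standardization statistics for features and label come from the training
split only, so the held-out 20% — on which MAE, Pearson r and R² are
reported — never leaks into preprocessing. Weights use He-scaled Gaussian
initialization; the whole procedure is a deterministic function of the
seed, which fixes the split, the initialization and the minibatch order.

Overfitting control is exposed, not hard-wired: with
`early_stopping_patience = p`, a 10% validation carve-out of the
*training* split (never the test split) is monitored and training stops
after p epochs without improvement, restoring the best weights. The
default leaves it off and trains the full schedule. On default synthetic
cohorts of n = 4000 the clock reaches held-out MAE ≈ 6.1 years, r ≈ 0.70,
R² ≈ 0.48 with early stopping at 100 scheduled epochs — deliberately in
the neighbourhood of published blood-marker clocks, because the
generator's marker signal-to-noise was calibrated once to support that
operating point.

## 3. Mediator scores

* **MDS** (0–9): one point per favorable component across nine diet
  components; component dichotomization follows the sex-specific
  sample-median convention for intake components.
* **DIS**: weighted sum of 19 a-priori food-group components
  (18 foods/beverages + 1 supplement group). **LIS**: weighted sum of four
  components — smoking (current vs former/never), leisure-time physical
  activity (MET-h/day, standardized, entered continuously by default with
  a sedentary-dichotomy switch), alcohol (heavy = > 14 g/day ethanol for
  women, > 28 g/day for men), and BMI (kg/m², standardized). Published
  weights are not shipped as defaults under anyone's name: `weight_table()`
  accepts user-supplied published weights, and
  `derive_inflammation_weights()` reproduces the derivation procedure —
  the panel of inflammatory biomarkers (hsCRP, IL-6, IL-8, IL-10 analogs)
  is collapsed to a standardized composite (unweighted mean of z-scores;
  the combination rule is a package decision, as the procedure's
  description does not fix one) and regressed jointly on all components
  with covariate adjustment; the coefficients are the weights. The
  package's own `default_*_weights` are synthetic values used by the
  generator, tagged as such.
* **Drinking (5 levels)**: non-response dominates; then lifetime
  abstainer / former drinker by history; current drinkers split at
  48 g/day into moderate and heavy.
* **SF-36 components**: the eight domain scores (0–100) are z-scored on
  the scoring sample, combined into two global scores by a weighted mean
  whose weights are the loadings of the two leading principal components
  of the domain correlation matrix (no rotation — PCA is named by the
  instrument's scoring tradition, rotation is not), and standardized to
  sample mean 50, SD 10. The component loading more heavily (in absolute
  share) on the four physical domains is labelled *physical*; signs are
  aligned so physical-domain loadings are positive on it. Item-level
  domain scoring is out of scope (the instrument's item weights are
  proprietary); domain scores are the unit of input.

## 4. Association models

Gaussian identity-link OLS throughout, since Δage is a continuous
year-scale outcome: Model 1 adjusts for CA and sex; Model 2 adds five
prevalent conditions (CVD, cancer, diabetes, hypertension, hyperlipidemia,
entered as two-level flags after upstream imputation); a sex-interaction
variant adds sex-by-trajectory terms; stratified fits run Model 2 within
one sex. Education and the lifestyle variables are deliberately *not*
covariates — education defines the exposure and lifestyles are candidate
mediators. Recruitment center enters the clock only, not the association
models (a switchable choice; the exposure definition gives no reason to
re-adjust for center downstream). The seven trajectory contrasts are
reported with unadjusted p-values, no multiplicity correction — the
contrasts answer one joint descriptive question, and this matches the
reporting convention of the analyses this package implements.

## 5. Counterfactual mediation

`estimate_effects()` implements the regression-based natural-effects
estimator. With exposure contrast *k* (vs `stable_high`), covariates C,
outcome model
E[Y | A, M, C] = θ₀ + θ₁ₐ + θ₂M + θ₃C and mediator model
E[M | A, C] = β₀ + β₁ₐ + β₂C:

* continuous mediator, no interaction: PNDE_k = θ₁ₖ, PNIE_k = θ₂β₁ₖ,
  TE_k = θ₁ₖ + θ₂β₁ₖ. In OLS this product-method TE coincides *exactly*
  with the difference-method TE (the exposure coefficient of the
  mediator-free outcome model) — the package asserts this equivalence to
  1e-8 in its tests, and TE = PNDE + PNIE holds exactly on every bootstrap
  replicate by construction.
* categorical mediator: the mediator model is multinomial logistic;
  PNIE_k = Σ_m θ₂ₘ (P̂(M=m | A=k, Cᵢ) − P̂(M=m | A=ref, Cᵢ)) averaged over
  the empirical covariate distribution.
* joint mediator set ("ALL"): TE from the mediator-free outcome model,
  PNDE from the fully mediator-adjusted one, PNIE = TE − PNDE. The
  difference method is used because mediator inter-correlations make a
  product-method joint PNIE ill-defined; no claim is made that the joint
  PNIE bounds the single-mediator ones.
* interaction case (single continuous mediator, opt-in): exposure-mediator
  product terms θ₄ₖ are carried, the direct effect is evaluated at the
  covariate-averaged reference mediator level, and TE = PNDE + TNIE.

**Inference.** Percentile bootstrap over participants (simple resampling
with replacement, matching how such analyses bootstrap; stratified
resampling is not the default). A resample leaving any trajectory level
with fewer than 2 rows is redrawn and counted in the diagnostics. The
default is 1000 resamples for effects and 100 for the interaction
pretest. P-values are two-sided bootstrap tail probabilities with add-one
smoothing; the pretest uses a bootstrap-normal p (mean/SD of the resampled
interaction coefficient), and the no-interaction estimator is adopted when
every pretest p exceeds 0.05.

**Proportion mediated.** PM = PNIE/TE × 100 on the linear scale, with a
percentile interval of the per-replicate ratio. The ratio-scale formula
`direct × (indirect − 1)/(total − 1)` — the proportion-eliminated formula
for odds-ratio-scale effects — is available behind
`proportion_mediated(..., formula = "ratio_scale")` for comparison, but it
is not meaningful for year-scale linear effects: applied to published
linear estimates it does not reproduce the published percentages, whereas
PNIE/TE reproduces every one within rounding
(`reference_mediation_estimates()` carries those published values, and the
test suite checks the agreement to 1.5 percentage points). PM is undefined
and flagged when the TE point estimate is 0.

## 6. The synthetic cohort generator

The generator is the package's test bed: seeded, and a pure function of
its configuration. Defaults are the study conditions the analysis
emulates:

* trajectory prevalences 891 : 198 : 590 : 703 : 426 : 289 : 282 : 1393
  (normalized), the composition of a 4772-participant analysis sample;
* chronological age truncated-normal on 35–100 with the location solved so
  the realized mean is 55.9 (SD 11.9) years; 48.2% men; 3 centers;
* per-trajectory means for LIS, DIS, MDS, physical activity, BMI and the
  SF-36 components taken from the published by-trajectory characteristics,
  with smoking and 5-level drinking compositions likewise;
* item-level MCAR missingness at published item rates (education 0.15%,
  physical activity 1.1%, food groups 5.2%, SF-36 domains 21.9%, …). MCAR
  is a modelling choice: only rates, not a mechanism, are reported for the
  data being emulated.

**Structural model.** The trajectory label is sampled *first* and the SES
indicators are then materialized consistently with it, which guarantees
the scorer round-trips 100% of rows (sampling indicators independently
would not). Δage follows a linear structural model: a direct trajectory
effect (default 0 to 0.83 years, calibrated so the downward and stably-low
total effects land near 1.28 and 0.75 years with mediated shares near 35%
and 73%) plus mediator loadings (years per mediator unit: LIS 0.5, DIS
0.09, MDS −0.12, BMI 0.07, SF-36 physical −0.045, others 0) times the
mediator deviations from their stable-high means, plus N(0, 7.4²) noise so
the realized Δage dispersion is realistic (SD ≈ 7.8). Blood markers are
linear-Gaussian in biological age (CA + Δage) with four deliberately
collinear derived markers; the dietary inflammation score is built
*exactly* as the weighted sum of 19 standardized food-group components
whose gradients are induced through the synthetic weights, so score
recomputation reproduces it to machine precision; MDS is an integer
round-clip of a latent normal, with component flags drawn consistently
with the integer score (and the ground truth uses the exact expectation of
the rounded-clipped normal); synthetic inflammatory biomarkers are a
weighted function of the pro-inflammatory lifestyle components plus
N(0, 0.5²) noise, so the weight-derivation procedure is recoverable.

The `GroundTruth` object carries the per-participant expected Δage and the
analytic per-trajectory decomposition (direct, per-mediator indirect,
total, proportion mediated), which the tests use for parameter recovery.

**What the generator does not emulate** — and therefore what passing tests
do not establish about real data: mediators are drawn independently of one
another within trajectory (real lifestyle variables correlate, which is
exactly why the joint indirect effect of real data is smaller than the sum
of single ones); marker covariance beyond the four built-in collinearities
is diagonal; missingness is MCAR rather than differential; recall error,
center effects and cohort selection are absent. Recovery on this generator
validates the estimators' plumbing and calibration, not the substantive
conclusions one would draw from any particular cohort.

## 7. Numerical choices and degenerate inputs

* Exact identities (Δage = BA − CA, TE = PNDE + PNIE, product ≡
  difference) are asserted at 1e-8 or to machine identity; statistical
  recoveries at 3 standard errors; SF-36 standardization at 1e-9.
* knn neighbour selection uses a stable sort; categorical imputation ties
  break by level order. Zero-range numeric columns contribute nothing to
  Gower distance.
* `lm.fit` singularities (collinear design columns) are errors naming the
  columns, not silent drops, in the mediation engine; constant disease
  flags are dropped with a warning in the association models; absent
  trajectory levels are dropped with a warning.
* The multinomial mediator model runs up to 300 IRLS/BFGS iterations;
  2-level categorical mediators use the same multinomial path for
  uniformity.
* Seeds: every stochastic routine takes an explicit integer seed; the
  pipeline fans a global seed out as seed + 1000 × stage-index, so any
  stage can be reproduced in isolation. The generator derives its
  missingness-masking stream from the config seed with a fixed large
  offset so structure and masking are independently stable.
* Problem sizes in the shipped tests were chosen to exercise the stated
  guarantees at meaningful scale: clock plumbing at n = 4000 with 100
  scheduled epochs; association and mediation recovery at n = 5000;
  proportion-mediated coverage over 50 simulation repeats of 200
  bootstraps; the imputation oracle at up to 200 rows.

## 8. Known limitations

* The mediation estimator is regression-based only; no
  imputation/weighting natural-effect estimators, no path-specific
  decompositions for ordered multiple mediators, and no adjustment for
  exposure-induced mediator-outcome confounders.
* Cross-sectional semantics: mediators and exposure are contemporaneous,
  so "mediation" is a model-based decomposition, not a temporal causal
  claim.
* The clock is a single systemic clock; no organ-specific or epigenetic
  clocks.
* SF-36 scoring starts from domain scores; the item-mean fallback for
  item-level data is non-standard and flagged as such.
* Parquet I/O requires the optional `arrow` package; CSV is the portable
  default.
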