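---
title: "Morphometric similarity networks: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric similarity networks: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery in `msnpain`: the network
constructions, the three discrimination models, the intensity predictor, the
synthetic cohort the test suite runs against, and the numerical and design
choices that the method descriptions leave open. It states no empirical
result beyond what the package's tests and `scripts/acceptance.R` compute.

## Network construction

**Morphometric similarity (MS).** A subject is given as a P × 9 table of
regional features (SA, GM, CT, MC, IC, FI, CI, FA, MD — mixed units:
mm², mm³, mm, dimensionless indices, and diffusion measures). Each feature
column is z-scored *across the regions of that subject* with the sample
(n − 1) SD, and the MS matrix entry for regions i, j is the Pearson
correlation between their nine-element standardized profiles. Two choices
here are conventions rather than givens:

- *Z-scoring axis.* Standardizing within subject (across regions) is the
  only choice that makes a single-subject network well defined without
  reference to other subjects; it also removes the wildly different feature
  units. Cross-subject standardization would make each subject's network
  depend on the cohort.
- *Sample vs. population SD.* Sample SD throughout, matching the ordinary
  Pearson estimator; the test oracles use the same convention, and the two
  differ only by a factor that cancels in the correlation itself.

The diagonal is set to exactly 1 and always excluded from derived summaries.
The mean similarity profile is mMS_j = (row sum − 1)/(P − 1).

**Functional connectivity (FC).** The same Pearson construction applied to
region-averaged BOLD series (P × T), giving FCN and mFC.

**Ensemble.** Each region's nine features (z-scored per feature across
regions, exactly as in MS) and its time series (z-scored within the region)
are concatenated to one vector of length 9 + T; the ensemble entry is the
weighted Pearson correlation with per-element weights w_ms on the feature
block and 1 − w_ms on the time block, normalized to sum one. Weighted means,
variances and covariances define the correlation. This particular
z-scoring split is the unique one under which w_ms = 1 reproduces the MS
matrix and w_ms = 0 the FC matrix to machine precision — both boundary
identities are asserted in the test suite. A consequence worth knowing: the
weights are per *element*, so at w_ms = 0.5 the time block dominates by
element count (T ≫ 9).

**Edge vectorization.** Edges are the strict upper triangle flattened
row-major: (1,2), (1,3), …, (1,P), (2,3), … This order is arbitrary but must
be identical across subjects and between fit and predict; it is fixed once
in `edge_index()`. Asymmetry beyond 1e−10 absolute is an error rather than
silently symmetrized. At P = 308, E = 47,278.

## Discrimination models

All models adjust for the same six covariates: age, sex, BMI, education
(binary), alcohol and exercise (ordinal 0–2).

**Univariable.** For each region, a linear model
`mMS_j ~ state + covariates` and the t-statistic of the state coefficient,
two-sided. A region is a replicated marker when p < α (default 0.05) in
both halves *with the same coefficient sign* — "replication" is read as
same-direction significance, which is stricter than two independent
rejections. No multiple-testing correction is applied by default (a
Bonferroni pass over P regions is a one-liner on the returned p-values);
the per-region result carries its df (N − 8) in an attribute.

**mMS multivariable.** Per-region logistic regressions
`state ~ mMS_j + covariates`, keeping the mMS coefficient β_j. A subject's
score is the bare dot product β·mMS — covariate coefficients and intercepts
are estimated but never enter the score. Perfect separation makes some
unpenalized per-region fits diverge; those regions are refit with a
ridge-stabilized IRLS (penalty ε = 1e−4 on all but the intercept) and their
indices reported in the fit object with a warning.

**MSN network model.** The subjects × edges matrix R is column-centered and
reduced by PCA. Centering makes the N-th component degenerate, so
K = min(N − 1, E) components are retained; the discarded null direction
carries no information. PCA is computed from the N × N Gram matrix (N ≪ E),
never from the E × E covariance. One logistic regression of state on all K
scores plus covariates is then fit. Because K ≈ N guarantees separation,
this fit is always ridge-stabilized with the same ε = 1e−4 (configurable and
recorded in the object); unpenalized maximum likelihood simply does not
exist here. Component coefficients are back-projected,
β_upper = V β_PCA, and a subject's score is (r − edge_mean)·β_upper. The
training-mean centering shifts every score by the same constant, so AUCs and
rank tests are unchanged relative to the uncentered dot product; the
centered form is kept because it makes the component-space and edge-space
scores *identical*, an algebraic identity the tests verify at 1e−8.

**Activation pattern.** Decoding weights β are not interpretable as a
forward map, so they are transformed to A = Σ_R β / var(ŝ), with Σ_R the
edge covariance and ŝ the training linear predictor. Σ_R (E × E, ~17 GB
dense at P = 308) is never materialized: A is computed as
Xᶜᵀ(Xᶜβ)/(N − 1)/var(ŝ). The factored and materialized forms agree at
1e−10 on small instances, and with identity covariance A reduces to
β/var(ŝ) exactly.

**Score orientation.** Patients are coded 1 in every fit, so fitted scores
are patients-high by construction; nothing is flipped after seeing an AUC.
For the univariable model the validation score is the discovery half's
largest-|t| region's mMS, signed by that region's discovery t.

## Intensity prediction (PCA-LASSO)

On patients only: R is centered and reduced exactly as above; the design is
the K component scores plus the six covariates; a Gaussian-family lasso path
is fit (glmnet) on a geometric grid of 100 penalties from λ_max — the
smallest penalty that zeroes every penalized coefficient, computed
analytically for the standardized problem — down four decades. λ is chosen
by leave-one-out cross-validation minimizing mean squared-error deviance
(the Gaussian deviance), the model is refit at λ on all patients, and
β_PCA is back-projected and Haufe-transformed as in the classifier.

Open choices, resolved as follows:

- *Standardization.* Predictors are standardized inside the lasso (the
  default of the routine family this follows). The PCA scores have
  variances spanning orders of magnitude; penalizing unstandardized scores
  makes the penalty a variance filter that discards low-variance components
  regardless of their association with intensity.
- *Covariates are penalized* along with the components by default — one
  penalized design, as when all regressors are handed to a lasso routine
  together. `penalize_covariates = FALSE` exempts them (the λ_max
  computation then residualizes intensity on the unpenalized block first).
- *Deviance* for the Gaussian family is the residual sum of squares.
- *Prediction conventions.* `predict()` returns
  intercept + (r − edge_mean)·β_upper + covariate terms;
  `score_only = TRUE` returns the bare uncentered dot product r·β_upper,
  which is the quantity whose correlation with observed intensity is the
  headline validation statistic.
- *RMSE.* The bare dot product lives on an arbitrary scale, so the default
  RMSE first recalibrates it onto the observed 0–100 scale by a univariate
  linear regression; `raw_rmse = TRUE` skips this. Both conventions are
  provided because the mapping from score scale to intensity scale is
  genuinely underdetermined.
- The λ grid is fit in full (no early path exit), which is what makes the
  λ → 0 end agree with unpenalized least squares on small designs — a
  property the tests check at 1e−6.

## Evaluation harness

AUC is computed by the rank-sum identity (ties count ½), which equals
Mann-Whitney U/(n₁n₀) and the trapezoidal area under the step ROC in the
absence of ties; the tests verify both identities. Group tests on scores:
equal-variance two-sample t (df = n₁ + n₂ − 2, so 134 at 68 + 68) or
Wilcoxon rank-sum with normal approximation; `method = "auto"` picks via
Shapiro-Wilk at 0.05 on pooled within-group residuals. Significance of a
prediction correlation against r = 0 uses the t-transform of Pearson r,
two-sided. `switch_halves()` refits everything with the halves exchanged;
`weight_sweep()` re-runs classifier and predictor per ensemble weight
(default grid 0, 0.1, …, 1). The shared-variance statistic between two
group-mean networks is 100·r² of their vectorized upper triangles.

## The synthetic cohort generator

The generator supplies the ground truth the whole test suite leans on. Its
defaults are the reference study design: P = 308 regions, T = 226 retained
BOLD samples, 68 subjects per arm per half (136 patients + 136 controls,
split evenly at random into discovery and validation), intensity on a 0–100
scale with noise SD 5, a standardized group shift of 1.5 on 10 regions, and
a 5-edge pain signal.

*Features.* Each subject's P × 9 table is a community-block latent-factor
draw: regions load mostly on their own community's factor (4 communities by
default), plus independent noise, scaled into plausible per-feature units.
This yields MS matrices with block structure without modeling real anatomy.

*Group effect.* Patients receive an additive shift of
effect_size × (feature SD) on the feature cells of the affected regions,
applied with a fixed alternating sign pattern (+, −, +, …) across the nine
features. The sign pattern matters: a shift that is uniform across a
region's features is invisible to Pearson correlation between regional
profiles (location invariance), so a uniform planting would leave the MS
pipeline nothing to find. The alternating pattern rotates the affected
regions' profiles instead, which is what a morphometric pathology entering
several features differently would do.

*Pain signal.* Every subject carries a latent severity factor that
modulates how strongly the first community's regions load on their shared
factor. This places a coherent, leading-variance direction into edge space
— the way real symptom severity expresses itself as network-level coupling
differences — and the default pain edges are pairs within that community.
Patient intensity is then computed from the subject's *own realized MSN
edges*: clamp(α + Σ_e γ_e·msn_e + ε, 0, 100), ε ~ N(0, pain_noise_sd),
with α set per cohort to center intensity near 50 (the observed patient
mean in this literature is ≈ 49–50/100). The clamp can introduce mild
nonlinearity at extreme draws; this is tolerated and rare at the default
noise level. Computing intensity from realized networks (not from latent
factors) makes the predictor's target exactly the structure the PCA-LASSO
assumes.

*Time series.* A latent-factor draw sharing only part of the feature
community structure (odd regions keep their community, even regions are
reassigned). The functional channel therefore carries no group effect and
no intensity signal: on synthetic cohorts the FC models are calibration
controls (AUC ≈ 0.5), and the generator's two mean networks share variance
only partially. Real data differ: empirically both channels carry disease
signal and their shared variance is much lower (a few percent); passing
tests on this generator show pipeline correctness and recoverability, not
that FC is uninformative in the world.

*Covariates.* Age ~ N(44, 13) truncated to 18–85, binary sex and
education, ordinal alcohol/exercise; `covariate_confounding` shifts their
distributions between arms to exercise the adjustment code. No matched
sampling is performed — covariates are drawn jointly, which sidesteps the
unspecified matching procedure of observational designs.

Determinism: all randomness passes through one seed; identical seeds give
bit-identical cohorts and splits (asserted in the tests).

## Problem sizes used by the test suite

The calibration and recovery simulations run at P = 60, T = 60 and
68 subjects per arm per half — 50 seeds for null calibration (validation
AUC of every model, and KS-uniformity of a fixed region's univariable
p-value) and 20 seeds for planted-effect recovery (model ordering and
held-out intensity correlation). The end-to-end smoke test and the
acceptance script run the full P = 308, 272-subject design once. These
sizes were chosen so the whole suite exercises the exact study geometry
where it matters (N, covariates, split) while keeping the seed loops at a
size a laptop runs in minutes.

## Known limitations

- The generator's planted effects are far stronger than real case-control
  morphometric differences; validation AUCs near 1 on synthetic data say
  nothing about achievable clinical AUCs.
- Single-edge sparsity of the planted pain signal is idealized; real
  intensity correlates are diffuse.
- The ridge ε = 1e−4 on (near-)separated logistic fits is a pragmatic
  stabilizer, not a tuned hyperparameter; coefficients at separation scale
  with 1/ε and only score *ranks* should be interpreted there.
- `evaluate_prediction()`'s recalibrated RMSE is an interpretation aid; it
  is not comparable across conventions with a raw-score RMSE.
- No anatomical labelling ships with the package: regions are positional
  labels, and edge maps are reported as index pairs.
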