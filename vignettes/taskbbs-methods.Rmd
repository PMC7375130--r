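---
title: "Predicting general cognitive ability from task activation maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting general cognitive ability from task activation maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taskbbs)
```

## Overview

`taskbbs` implements an end-to-end pipeline for predicting a general
cognitive ability (GCA) factor from per-subject task-fMRI contrast maps
with Brain Basis Set (BBS) modeling. The pipeline has five scientific
components:

1. a **bifactor measurement model** that extracts a general factor from a
   ten-test behavioral battery;
2. the **BBS predictive model**: principal-component brain features entered
   jointly with nuisance covariates into an ordinary-least-squares
   regression;
3. **family-aware ten-fold cross-validation** with every model component —
   including the factor model — refit inside each training fold;
4. **Freedman–Lane permutation inference** for the pooled cross-validated
   correlation; and
5. a **network-demand meta-analysis** relating each task contrast's mean
   frontoparietal (FPN) activation and default-mode (DMN) deactivation to
   how well that contrast predicts GCA.

Because the motivating data (family-structured human neuroimaging cohorts)
are access-restricted, the package ships a first-class synthetic-data
generator that emulates their statistical structure. Every stage of the
pipeline is exercised and tested against that generator.

## The GCA factor

The behavioral battery consists of ten tests. `fit_bifactor()` fits an
exploratory bifactor model in four steps:

1. maximum-likelihood exploratory factor analysis with four factors on the
   train-set correlation matrix (`stats::factanal`);
2. oblimin (quartimin, $\gamma = 0$) rotation by gradient projection;
3. a one-factor ML EFA of the resulting factor correlation matrix
   $\Phi$ (the second-order model, loadings $\ell$); and
4. the Schmid–Leiman transformation,
   $\Lambda_g = \Lambda_1 \ell$ and
   $\Lambda_f = \Lambda_1\,\mathrm{diag}\!\left(\sqrt{1-\ell^2}\right)$,
   which splits each test's common variance into a general part and an
   orthogonal group part.

Subjects are scored on the general factor with the regression (Thurstone)
method, $W = R^{-1}\Lambda_g$, applied to test scores standardized with the
**train-set** means and SDs. The package always carries the train
standardization statistics to held-out subjects; re-standardizing on a test
set would leak test-set information into the scores, and the alternative is
available only through `use_train_stats = FALSE` for fitting contexts.

Model quality is summarized by omega hierarchical,
$$\omega_h = \frac{(\sum_j \lambda_{g,j})^2}
 {(\sum_j \lambda_{g,j})^2 + \sum_f (\sum_j \lambda_{f,jf})^2 + \sum_j \psi_j},$$
the SRMR of the implied versus observed correlation matrix, and — when a
retest session exists — the test–retest ICC(2,1) of the factor scores
(two-way random effects, absolute agreement, single measure).

Numerical notes:

* The rotation is a gradient-projection minimization of the quartimin
  criterion, warm-started at the varimax solution plus a fixed set of
  pseudo-random orthogonal starts (deterministic, so results do not depend
  on the caller's RNG state); the lowest-criterion solution wins. The inner
  loop is compiled (RcppArmadillo); an R reference implementation is kept
  and the two are asserted equal in the tests. Convergence is declared at a
  projected-gradient norm below `1e-5`.
* The number of group factors is fixed at four; no automatic selection.
* ML EFA refits inside permutation loops are warm-started at the observed
  fit's uniquenesses (a pure speed optimization; a failed warm start falls
  back to a cold start).
* Heywood-boundary solutions (uniqueness at the `factanal` lower bound) are
  flagged, not silently accepted.
* The Schmid–Leiman solution preserves, exactly, the communalities implied
  by the hierarchical (second-order) model. It equals the first-order
  oblique communality only insofar as the one-factor model reproduces
  $\Phi$; with four group factors that model has two degrees of freedom, so
  the identity is approximate and is tested at a realistic 0.05 rather
  than machine precision.
* An optional MMSE < 26 row filter mirrors the conventional inclusion rule
  for this battery.

## Brain Basis Set modeling

For one task contrast, the train subjects' maps form an $n \times m$
matrix. `build_basis()` centers each voxel at its train mean (no variance
scaling — the convention of the reference PCA implementations this follows)
and takes the top $K$ right singular vectors; $K$ defaults to 75, the
component count this modeling tradition uses, and is clipped with a warning
when it exceeds the PCA rank bound. Each component's sign is fixed so its
largest-magnitude voxel loading is positive, making bases reproducible.
Expression scores are projections of (train-centered) maps onto the
components, identically for train and test maps.

The generative regression model is
$$y = X\beta + Z\gamma + \varepsilon,$$
with $X$ the expression scores, $Z$ the covariate design (intercept; age,
age², handedness, brain volume, task-specific mean framewise displacement
and its square, all z-scored with train statistics; gender and
reconstruction version dummy-coded), fit jointly by OLS. Out of sample,
only train-estimated coefficients are used:
$\tilde y = y_{test} - Z_{test}\hat\gamma$ (the covariate-adjusted
response) and $\hat y = X_{test}\hat\beta$ (its brain-based prediction).

With $K = n_{train} - 1$ and an intercept-only $Z$, BBS prediction is
algebraically the minimal-norm least-squares solution on the centered voxel
matrix; the acceptance suite verifies this against a pseudoinverse oracle
at $10^{-8}$.

The justification for a ~75-dimensional basis is an intrinsic
dimensionality argument: `estimate_intrinsic_dimension()` implements the
Levina–Bickel maximum-likelihood estimator,
$$\hat m_k(x) = \left[\frac{1}{k-1}\sum_{j=1}^{k-1}
  \log\frac{T_k(x)}{T_j(x)}\right]^{-1},$$
averaged over points and over $k \in [10, 20]$ (the original
recommendation; configurable). Local estimates are averaged directly by
default; averaging the inverses first is available as `average =
"inverse"`. Neighbor search is exact — the matrices involved here have at
most a few thousand rows.

`consensus_map()` visualizes a fitted model as
$z\!\left(\sum_k \hat\beta_k c_k\right)$, the β-weighted component sum
z-scored over voxels.

## Cross-validation and inference

`make_family_folds()` shuffles families (seeded) and assigns each greedily
to the currently smallest fold, so siblings never straddle a train/test
boundary and fold sizes differ by at most the largest family size.

`run_cv()` runs the complete per-fold pipeline — bifactor refit, GCA
scoring of train and test subjects with train statistics, basis
construction, covariate standardization, joint OLS — entirely on training
data. Per-fold correlations $r_f = \mathrm{cor}(\tilde y, \hat y)$ are
pooled by Fisher averaging, $\bar r = \tanh(\mathrm{mean}(\tanh^{-1}
r_f))$. Alongside:

* $R^2_{cv} = 1 - \sum(\tilde y - \hat y)^2 / \sum(\tilde y - \bar
  y_{train})^2$, with $\bar y_{train}$ the covariate-adjusted train mean.
  The adjusted mean is used (rather than the raw train mean) because the
  intercept lives in $Z$, which makes $\tilde y$ train-centered up to the
  brain fit and keeps $R^2_{cv}$ well defined; both quantities are near
  zero in practice.
* $MSE = \sum(\tilde y - \hat y)^2/(n-1)$.
* A fold-based interval $\bar r \pm z_{0.975}\,SD(r_f)$. The literal SD is
  the default; `scale = "sem"` switches to the standard error, since the
  verbal convention this follows is ambiguous between the two.

Per-fold $R^2_{cv}$ and MSE are averaged arithmetically.

`permutation_test()` implements Freedman–Lane for the pooled correlation.
The nuisance-only model is fit **once per iteration on the full sample**:
each of the ten behavioral test columns is residualized on the covariate
design, the residual rows are permuted jointly, and the permuted residuals
are added back to the covariate fits. The entire cross-validation — factor
refit per fold included — is rerun on the reconstructed scores. Permuting
the raw ten-test rows (pre-factor) keeps the exchangeability unit at the
subject level while preserving covariate effects. Permutation is performed
globally before fold splitting; permuting within folds would change the
exchangeability unit. Family structure is ignored in the permutation
(subjects are treated as exchangeable under the null); a within-family
restriction would be a straightforward extension but is not implemented.

The p-value is the rank convention `count(null >= observed) / B`; an
observed statistic exceeding every null draw is reported as `p < 1/B`
(`exceeds_all = TRUE`). The `(count+1)/(B+1)` correction is deliberately
not applied, to match the rank convention of the analysis this package
reproduces; the difference is at most `1/B`. `B` defaults to 10,000 and
should be reduced for interactive work.

## Network-demand meta-analysis

For each contrast, `network_means()` averages the subject-average map over
each network of a seven-network parcellation (subject-average first;
with equal weights this equals averaging per-subject means).
`demand_accuracy_correlation()` then correlates a network's mean activation
with the contrast's prediction accuracy (the pooled CV correlation — the
accuracy metric is fixed to that) across contrasts, and
`demand_regression()` fits accuracy on FPN and DMN activation jointly,
reporting the fitted-versus-observed correlation.

## The synthetic cohort generator

`synth_spec()` + `generate_cohort()` / `generate_contrast_maps()` /
`generate_roi_timeseries()` produce seeded cohorts with the structure the
analysis assumes:

* **Families** drawn from a configurable size distribution (defaults:
  sizes 1–5 with probabilities 0.55/0.25/0.12/0.06/0.02 — invented
  configuration, chosen to give a realistic mix of singletons and sibships;
  the true family-size distribution of the motivating cohort is not
  public). The latent ability $g$ has a family-shared variance share
  `family_icc` (default 0.3, in the range expected for a heritable trait
  in a sibling design).
* **Behavior**: ten tests named after the standard battery, generated from
  a bifactor truth (default general loadings 0.7, group loadings 0.4 in
  blocks crystallized/speed/memory/visuospatial of sizes 2/3/3/2 — these
  defaults are configuration, not estimates), unit variance per test, plus
  a retest session with per-test reliability `retest_reliability`
  (default 0.78). Note the ICC of *factor scores* across sessions is
  naturally higher than the per-test reliability, since scoring averages
  unique noise away.
* **Maps**: voxel vectors with a 1-D ordering grouped into seven contiguous
  network blocks (full 3-D geometry is irrelevant to every downstream
  computation, which treats maps as vectors; smoothness is induced by
  moving-average kernels within network blocks). Each map is a
  demand-scaled FPN-positive/DMN-negative activation pattern, plus
  subject-specific expressions of smooth unit-norm component patterns —
  component 1's expression is `gca_coupling * demand * g` plus unit noise,
  so the g-related signal grows with cognitive demand — plus a motion
  confound `confound_strength * meanFD` times a fixed pattern, plus i.i.d.
  voxel noise. The motion propensity also enters $g$ negatively, so the
  covariate model has real work to do.
* **Demand levels**: fifteen contrasts named after the standard seven-task
  battery with demand levels between 0.95 (2-back vs 0-back) and 0.10 —
  configuration chosen so executive contrasts are the most demanding.
* **Resting-state**: ROI time series from a low-rank latent covariance in
  which one network mode's expression carries the trait signal — weakly
  (an order of magnitude below the task-map coupling) and blurred by
  session-specific noise on that same mode, which caps the trait
  information a connectome can carry however many edges are measured.
  Connectome-based prediction therefore lands below task-based prediction,
  mirroring the empirical ordering of the two modalities. Alongside the
  time series come drifting rigid-body motion traces with injected spike
  frames and noise-tissue surrogate signals, so
  framewise-displacement screening, scrubbing, band-pass filtering
  (4th-order zero-phase Butterworth), CompCor-style nuisance regression
  and Fisher-z connectome construction are all exercised. Band-pass is
  applied before scrubbing, with no interpolation over censored frames
  (the censored frames simply do not enter the correlations).

What the generator does **not** emulate: hemodynamics and task timing,
3-D spatial geometry and registration error, non-Gaussian score
distributions, missing data, site/scanner batch effects. Tests passing on
synthetic cohorts therefore validate the *statistical machinery* — leak-free
cross-validation, calibrated inference, unbiased recovery under the assumed
model — not robustness to every property of real imaging data.

## Problem sizes in the test suite

The test and acceptance suites run the full procedures at desk scale,
chosen so the whole suite completes in minutes on one core: null
calibration uses 200 replicate cohorts of n = 300 with 99 permutations and
5 folds on 120-voxel maps; signal recovery compares a 10-fold CV at n = 800
against a 20,000-subject single-split population oracle; the demand
analysis uses ten seeds of a 15-contrast suite at n = 150. The
`scripts/acceptance.R` study runs n = 500 subjects, 800 voxels, K = 40 and
99 permutations per contrast. These sizes are the package's own choices;
all of them are configuration, and the defaults of `synth_spec()` and
`study_config()` (n = 967, m = 2000, K = 75, 10 folds) mirror the study
design the pipeline reproduces.

## Known limitations

* The bifactor EFA inherits `factanal`'s behavior on boundary solutions;
  overspecified models on data without group structure can park chance
  doublets in group factors (flagged via `heywood`).
* OLS-based BBS assumes $K \ll n$; no regularized variant is provided.
* The permutation test treats subjects as exchangeable under the null;
  family-restricted permutation is not implemented.
* CFI/RMSEA/BIC fit indices would require full SEM machinery and are out of
  scope; SRMR is the implemented fit check.
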