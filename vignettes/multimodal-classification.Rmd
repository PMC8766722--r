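---
title: "Multimodal classification of Alzheimer's disease from ROI features: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal classification of Alzheimer's disease from ROI features: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofuse)
```

## The problem

Diagnostic classification of Alzheimer's disease (AD) versus cognitively
normal (CN) subjects is increasingly built on quantitative region-of-interest
(ROI) features: gray-matter volumes and cortical thickness from structural
MRI, regional standard-uptake-value ratios (SUVR) from amyloid PET, and
fractional anisotropy (FA) or mean diffusivity (MD) from diffusion tensor
imaging. Clinical cohorts in this setting are small — a few tens of subjects
per group — while each modality provides tens to hundreds of features, so any
credible classifier needs aggressive feature selection, careful
leakage-free evaluation, and a principled way to combine modalities.

`neurofuse` implements that analysis end to end:

1. **Feature selection** per modality — an embedded method (EBM) based on
   random-subset random-forest importance, a filter method (FBM) based on
   two-sample t-tests, and a common two-stage Pearson-correlation redundancy
   filter.
2. **Classification** per modality — training-set standardization followed by
   an RBF-kernel support vector machine, evaluated by repeated stratified
   80/20 holdout with mean ROC / AUC.
3. **Late fusion** — a convex weighted combination of the per-modality AD
   probabilities, \(Y_i = \sum_k c_k\, y_{ki}\) with \(c_k \in [0,1]\),
   \(\sum_k c_k = 1\), evaluated for every modality subset at equal weights.
4. **Synthetic cohorts** — a generator with planted effects and a controlled
   cross-modality redundancy structure, so every step can be validated
   against known ground truth.

## The synthetic cohort generator

Real multimodal AD cohorts of this kind are private; the generator provides
cohorts with the statistical structure the analysis assumes while keeping
every moment analytically tractable. It is a Gaussian linear factor model in
which every feature has unit total variance. For subject \(i\) with group
indicator \(g_i \in \{0, 1\}\) (CN/AD) and a shared latent factor
\(L_i \sim N(0,1)\):

* an *informative* feature of a modality with loading \(\lambda\) is
  \(x_{ij} = d\,g_i + \lambda L_i + \sqrt{1 - \lambda^2}\,\varepsilon_{ij}\),
* a *nuisance* feature in block \(b\) is
  \(x_{ij} = \sqrt{\rho}\,B_{ib} + \sqrt{1-\rho}\,\varepsilon_{ij}\),

with all \(\varepsilon, B, L\) independent standard normal. Consequences
used by the test-suite oracles: the within-group correlation between
informative features of two modalities with loadings \(\lambda_1,
\lambda_2\) is exactly \(\lambda_1 \lambda_2\); within-block nuisance
correlation is \(\rho\); the standardized group separation of an informative
feature is \(d\).

Design notes:

* The latent factor and the block factor are **not** stacked on the same
  feature: with a strong loading (e.g. \(\lambda = 0.95\)) and a moderate
  \(\rho\) the two variance shares would exceed 1. Informative features
  carry the latent factor; nuisance features carry the block structure.
  This keeps unit variance exact and every moment closed-form.
* The latent factor models *redundant pathology*: two modalities with high
  loadings see correlated noise, so their classifiers make correlated
  errors and fusing them cannot help — the mechanism behind the empirical
  observation that amyloid-PET and DTI do not complement each other, while
  modalities with independent signal do fuse synergistically.
* Subject identifiers are shared across modalities (full overlap);
  `dropout_fraction` removes a random subject fraction per modality to
  emulate partial multimodal coverage. Ensemble evaluation inner-joins on
  identifiers, so partial overlap degrades gracefully.
* An *external* cohort is drawn from a separate seed stream with an additive
  mean shift and a multiplicative dispersion change applied to all features,
  emulating a scanner/protocol shift. It reuses the internal mechanism, so
  `external_shift = 0, external_scale = 1` is distributionally identical to
  the internal generator.
* Units are abstract: all features are generated on a unit-variance scale
  because the classifier standardizes anyway; physical units (mm³, SUVR,
  FA) would be labels only.
* The generator emulates group separation, within-modality redundancy and
  cross-modality redundancy. It does **not** emulate heavy tails, outliers,
  site batch structure within a cohort, missing values, or covariate
  effects (age, sex) — passing tests therefore demonstrate correctness of
  the pipeline's algorithms, not robustness of SVM classification to those
  real-data pathologies.
* Inter-feature correlation of real ROI tables is not characterized in the
  motivating study; `block_rho` defaults are free modelling parameters, not
  estimates.

## Feature selection

Both routes end in the same correlation filter and the same cap.

**EBM (embedded).** At each of `n_runs = 2000` iterations the subjects are
split into a balanced (class-stratified) random 80/20 partition — mirroring
the environment the final classifier is trained in — a uniform random subset
of `subset_size = 8` features is drawn, and a 500-tree random forest is
fitted on the training portion. The impurity (mean decrease in Gini)
importance of each participating feature is recorded; a feature's final
importance is its mean over the iterations in which it appeared. Features
with importance strictly below `0.55 ×` the top importance are removed (the
boundary value survives), and survivors are ranked by descending importance.
The tree count (500) and impurity importance are fixed choices for
reproducibility; the method itself only requires "a random forest". One
level of 2,000 iterations is implemented; there is no outer replication
loop.

**FBM (filter).** A two-sided two-sample t-test per feature compares the AD
and CN groups; features with \(p > 0.05\) are removed and survivors ranked
by descending \(|t|\). The classical equal-variance Student form is the
default (`var_equal = TRUE`), with Welch behind the switch; the sign of
\(t\) carries no selection meaning, so the ranking uses its magnitude.

**Correlation pruning.** Pearson correlations are computed over all subjects
pooled, on raw (pre-standardization) values — pruning precedes
standardization in the pipeline. Stage 1 removes every feature with
\(|r| > 0.55\) against the top-ranked feature (which always survives).
Stage 2 walks the surviving list in rank order from the second feature on;
each anchor removes any lower-ranked survivor with \(|r| > 0.70\) against
it. Both rules are strict inequalities. The last surviving feature is never
a useful anchor (nothing ranks below it), so the walk's stopping point is
immaterial under this greedy formulation.

Finally the ranked survivors are truncated to `max_features = 8` (one
feature per five cases at \(n \approx 40\)); shorter lists are returned
as-is. The stage order — ranking filter, then the \(r\)-top stage, then the
pairwise stage, then truncation — is fixed and tested. Every removal is
recorded with its stage and anchor, and ties in any ranking are broken
lexicographically on the feature name so results are deterministic.

## Classification and evaluation

**Standardization.** Each feature is centred and scaled,
\(x' = (x - \bar{x})/s\), with \(\bar{x}\) and \(s\) (sample SD, \(n-1\))
estimated on *training subjects only*. Test and external subjects are always
transformed with training parameters — never refit — so an injected external
shift remains visible after transformation. A constant training feature is
an error naming the feature.

**SVM.** RBF kernel with `C = 0.1` — deliberately not the common library
default of 1; it is the protocol's stated value — and
`gamma = "scale"`, defined explicitly as
\(1 / (p \cdot \overline{\mathrm{Var}})\) where \(p\) is the number of
features and \(\overline{\mathrm{Var}}\) the mean per-feature variance of
the training matrix (equal to \(1/p\) after standardization). An SVM outputs
decision values, not probabilities; any monotone map to \([0,1]\) satisfies
the fusion contract, and the package fits a logistic sigmoid on the training
decision values (recorded in the model object). Degenerate decision values
fall back to an intercept-only fit. The decision threshold is 0.5 with ties
classified as AD — a symmetric, documented rule.

**Repeated holdout.** Each of `n_cycles = 2000` cycles draws a fresh
class-stratified 80/20 split (per-class test counts rounded to nearest, at
least one test subject per class), refits standardization, SVM and
calibration on the training portion only, and scores the test portion:
accuracy, sensitivity, specificity, balanced accuracy (AD is the positive
class), and the ROC/AUC of the probabilities. Per-cycle seeds derive
deterministically from the master seed, so the whole evaluation is
bit-reproducible.

**ROC conventions.** The ROC is a threshold sweep over unique scores (tied
scores cross the threshold together); AUC is the trapezoidal integral,
which equals the Mann–Whitney statistic \(U/(n_1 n_0)\) with ties credited
1/2 — the suite asserts this equivalence to \(10^{-12}\) against an
independently coded rank-sum oracle. The mean ROC is computed by *vertical
averaging*: each curve is evaluated on a fixed FPR grid (101 points, step
0.01) as the step function it is, anchored at (0,0) and (1,1) with the
upper envelope taken at vertical segments, and TPRs are averaged pointwise.
The averaging convention and the grid are design choices of this package;
nothing in the underlying protocol pins them down.

## Late fusion

Per-modality probabilities are combined as \(Y_i = \sum_k c_k y_{ki}\)
with convex weights. `enumerate_combinations()` evaluates every modality
subset of size ≥ 2 at equal weights (1/2 for pairs, 1/3 for the triple)
next to each single-modality baseline on the same inner-joined subjects.
The fused ROC/AUC is computed from the fused probability (not by averaging
the base ROCs). Base models enter fusion trained once on the full
model-building cohort and are applied to a *disjoint* held-out ensemble
cohort, mirroring a design where a separate ensemble group with complete
multimodal coverage exists. Weight grids beyond equal weights are available
via `sweep_weights()` but are not part of the default protocol.

Exact algebraic properties — convexity of \(Y\), permutation equivariance,
linearity in the weights, and bit-exact agreement of a one-hot weight vector
with the corresponding base classifier — are asserted in the test suite at
\(10^{-12}\).

## The end-to-end experiment

`run_experiment()` chains the stages: simulate three disjoint cohorts
(model-building, ensemble, external) from derived seed streams; select
features per modality; run the repeated-holdout evaluation per modality;
train final models on the full model-building cohort; evaluate all
equal-weight combinations on the ensemble cohort; score models and the
all-modality ensemble on the external cohort. Every artifact (selection
audit JSON, metric JSON/CSV, mean-ROC CSV, run manifest with config, seed
and versions) is written to the output directory and is byte-identical
across reruns with the same config and seed. A single-modality config skips
the ensemble stage with a logged notice; any stage failure propagates with
the stage name attached.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise the pipeline at the study
conditions the package is designed for: balanced cohorts of 20 subjects per
group; modality sizes of 142 (sMRI-like), 19 (PET-like) and 84 (DTI-like)
features in the end-to-end run; 2,000 selection iterations and 2,000
evaluation cycles where the protocol value matters (chance calibration,
planted-feature recovery, importance convergence); and reduced cycle counts
(tens to hundreds) in unit tests whose assertions do not depend on Monte
Carlo depth. Planted-recovery and synergy/redundancy properties are averaged
over 20 independent cohort seeds.

## Known limitations

* Probability calibration is a training-set sigmoid; with perfectly
  separable training data it saturates and probabilities approach 0/1.
  Fusion only requires a monotone map, but the fused values should not be
  read as calibrated posterior probabilities.
* The repeated-holdout protocol evaluates the *procedure* on one cohort; at
  \(n = 40\) the per-cycle test sets (4 + 4 subjects) make per-cycle metrics
  extremely coarse, which is why only their means and dispersions are
  reported. More fundamentally, the split-averaged accuracy converges to a
  *cohort-conditional* value, not the population value: on zero-effect
  cohorts of this size the cohort-conditional mean accuracy scatters around
  chance with a standard deviation near 0.07, so a single cohort's
  2,000-cycle average can sit a few points away from 0.50 without any
  implementation bias. Calibration claims should always be averaged over
  independent cohorts, as the test suite does.
* Feature selection is run once on the full model-building cohort, not
  inside each holdout cycle; selection therefore sees the evaluation
  subjects. This mirrors the original protocol and is one reason external
  validation on a shifted cohort is part of the pipeline.
* No wrapper-based (search) feature selection, no kernel or hyperparameter
  tuning, no stacking ensembles: the protocol fixes the kernel, `C`,
  `gamma`, and a non-generative weighted fusion.
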