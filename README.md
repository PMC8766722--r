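# neurofuse

Multimodal classification of Alzheimer's disease (AD) versus cognitively
normal (CN) subjects from region-of-interest (ROI) imaging features —
gray-matter volumes and cortical thickness (structural MRI), regional
standard-uptake-value ratios (amyloid PET), and fractional anisotropy /
mean diffusivity (DTI). The package is aimed at neuroimaging groups working
with small balanced clinical cohorts (tens of subjects) and feature tables
of tens to hundreds of ROIs per modality, who need leakage-aware feature
selection and evaluation, and a principled way to ask whether combining
modalities actually helps.

## What it implements

**Feature selection per modality**, two routes ending in a common
redundancy filter:

* *Embedded (EBM)*: 2,000 iterations, each drawing a balanced random
  subject split and a uniform random subset of 8 features, fitting a
  500-tree random forest, and recording impurity importances. A feature's
  score is its mean importance over appearances; features below 0.55 × the
  top score are removed.
* *Filter (FBM)*: a two-sample Student t-test per feature; features with
  p > 0.05 are removed, survivors ranked by |t|.
* *Correlation pruning* (both routes): on the raw values, drop features
  with |r| > 0.55 against the top-ranked feature, then walk the surviving
  ranking and let each feature drop lower-ranked survivors with |r| > 0.70;
  finally cap at 8 features.

**Per-modality classifier**: features standardized to zero mean and unit
variance with training-set parameters (x′ = (x − x̄)/s, never refit on test
or external data), then an RBF-kernel SVM with C = 0.1 and
gamma = 1/(p · mean feature variance), with a sigmoid probability
calibration fitted on training decision values. Performance is estimated by
2,000 repeated stratified 80/20 holdout cycles, reporting mean ± SD
accuracy, sensitivity, specificity, balanced accuracy, AUC, and the
vertically averaged mean ROC curve.

**Weighted late fusion**: per-modality AD probabilities are combined as

    Y_i = c1·y1i + c2·y2i + c3·y3i,   c_k ∈ [0,1],  Σ c_k = 1

and every modality subset is evaluated at equal weights (1/2 for pairs, 1/3
for the triple) against the single-modality baselines on a held-out
ensemble cohort. Redundant modalities (classifiers with correlated errors)
show no fusion gain; modalities with independent signal do.

**Synthetic cohort generator**: a Gaussian linear factor model with planted
informative features (standardized effect size d), block-correlated
nuisance features, an optional shared latent factor that makes two
modalities redundant by construction, and a distribution-shifted external
cohort — so every pipeline stage can be validated against closed-form
ground truth.

## Worked example

```r
library(neurofuse)

cohort <- cohort_config(
  n_per_group = 20,
  modalities = list(
    modality_spec("smri", 60, n_informative = 8, effect_size = 1.5,
                  block_size = 5, block_rho = 0.3),
    modality_spec("pet", 19, n_informative = 4, effect_size = 1.5,
                  latent_loading = 0.7),
    modality_spec("dti", 40, n_informative = 6, effect_size = 1.0,
                  latent_loading = 0.7)
  ), seed = 42)
coh <- generate_multimodal_cohort(cohort)

sel <- select_features(coh$tables$pet, selection_config("ebm", n_runs = 500))
sel
#> <selection_result> [ebm] 1 feature(s) selected for 'pet'
#>   selected: pet_roi003
#>   removed:  importance_filter (16), r_top (2)

ev <- repeated_holdout_evaluation(coh$tables$pet, sel$selected,
                                  config = eval_config(n_cycles = 500))
ev
#> <holdout_eval> 'pet': 500 cycles, 1 features
#>   accuracy           0.870 +/- 0.111
#>   sensitivity        0.817 +/- 0.193
#>   specificity        0.922 +/- 0.135
#>   balanced_accuracy  0.870 +/- 0.111
#>   auc                0.879 +/- 0.135
```

The selection audit says 16 of the 19 PET features fell at the importance
filter and 2 more were pruned as correlates of the top feature; the
surviving feature alone classifies at mean AUC 0.879 over 500 random 80/20
splits. Training final models per modality and fusing them on a disjoint
ensemble cohort:

```r
ens <- generate_multimodal_cohort(cohort_config(20, cohort$modalities, seed = 43))
models <- lapply(names(coh$tables), function(m)
  train_modality_model(coh$tables[[m]],
    select_features(coh$tables[[m]], selection_config("ebm", n_runs = 500))$selected))
names(models) <- names(coh$tables)
enumerate_combinations(models, ens$tables)
#> <combination_report>
#>    modalities accuracy sensitivity specificity balanced_accuracy    auc
#>          smri    0.975        1.00        0.95             0.975 1.0000
#>           pet    0.775        0.75        0.80             0.775 0.8800
#>           dti    0.550        0.75        0.35             0.550 0.6275
#>      smri+pet    0.975        1.00        0.95             0.975 1.0000
#>      smri+dti    0.975        1.00        0.95             0.975 1.0000
#>       pet+dti    0.700        0.80        0.60             0.700 0.8100
#>  smri+pet+dti    0.900        0.95        0.85             0.900 0.9800
```

Here `pet` and `dti` were generated with a shared latent factor
(`latent_loading = 0.7`), so their classifiers make correlated errors:
fusing them (AUC 0.81) does not improve on PET alone (0.88), while either
fused with the independent-signal `smri` matches the best single modality.
That is exactly the redundancy-versus-synergy behaviour the fusion stage is
designed to expose.

The whole experiment — three disjoint cohorts, selection, evaluation, final
models, all fusion combinations, external validation, artifacts on disk —
runs as one call:

```r
run_experiment(experiment_config(cohort, seed = 42), "results/run1")
```

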