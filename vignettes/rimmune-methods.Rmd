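---
title: "rimmune methods: generative model, feature definitions, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rimmune methods: generative model, feature definitions, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rimmune)
```

This vignette documents what `rimmune` computes and why: the synthetic
generative model, the 239-feature radiomic catalog, the ssGSEA scoring and
labeling scheme, and the 0.632-bootstrap evaluation and model-selection
machinery. Code chunks are illustrative and not evaluated at build time; the
full pipeline runs in a few minutes on one CPU.

## 1. The generative model

Every sample has a latent immune state — independent standard-normal
`th1_level`, `th2_level`, and `ctl_level` — drawn reproducibly from a
per-sample seed derived by hashing the master seed with the sample id. Both
data arms (image and expression) are generated from this shared state, so
any association between them is planted, known, and recoverable.

### 1.1 Phantom tumors

`phantom_config()` / `generate_cohort()` produce quasi-ellipsoidal tumors on
a CT-like Hounsfield-unit (HU) grid. The intensity model is

```
I(x) = background + (plateau(x) + texture(x) - background) * ramp(x)
ramp(x) = 1 / (1 + exp(d_out(x) / s))
```

where `d_out` is the signed distance outward from the tumor boundary
(computed from the ellipsoid level-set as `(rho - 1) * rho / |grad rho|`) and
`s = margin_width_mm / (2 * log 9)` converts the configured 10%-to-90%
margin width into the logistic scale. The plateau is `core_mean_hu` deep
inside and rises to `rim_mean_hu` near the boundary; texture is a
Gaussian-smoothed, skew-transformed stationary noise field.

Key parameters (defaults in parentheses):

- `grid_shape` (40³ voxels), `spacing_mm` (1.5 mm isotropic): small enough
  for seconds-per-volume extraction, large enough that the rim, core, and
  margin are all resolved.
- `tumor_radius_mm` (12), with per-sample anisotropic radius jitter: the
  "quasi" in quasi-ellipsoid.
- `background_hu` (−800, aerated lung), `core_mean_hu` (30, soft tissue),
  `rim_mean_hu` (30), `noise_sd_hu` (25): CT-plausible contrasts.
- `margin_width_mm` (2): the 10–90% rise distance of the logistic ramp.
- `coupling_beta` (0): the planted image–immune coupling. The rim mean gains
  `coupling_beta * th2_level` HU, and the margin width shrinks by the factor
  `exp(-0.02 * coupling_beta * th2_level)`. At `coupling_beta = 36` (the
  pipeline default, ≈ 1.4 texture SDs per latent SD) the coupling dominates
  the texture noise; at 0 image and immune state are independent.

### 1.2 Expression and gene sets

`immune_gene_sets()` builds 28 disjoint synthetic signatures of
`set_size = 20` genes in an `n_genes = 5000` universe, including the three
designated targets "Th1 cells", "Th2 cells", and "Cytotoxic cells".
`generate_expression()` draws a noise matrix and shifts each designated
set's genes by `effect_size` (default 2) times its latent; the remaining 25
sets are unshifted background. GMT read/write helpers round-trip the sets.

## 2. The 239-feature catalog

`feature_catalog()` enumerates 239 uniquely named features:

| group | n | content |
|---|---|---|
| physical | 3 | volume (mm³), a mass surrogate (volume × mean(HU+1000)/1000), largest axial cross-section |
| histogram | 59 | 11 statistics × 5 regions, + 4 extra percentiles for the total region |
| shape | 10 | surface area, sphericity, compactness, diameters, elongation, flatness, ... |
| local texture | 95 | GLCM (26 statistics × 2 distances), GLRLM/GLSZM (16 each), NGTDM (5), GLDM (6) |
| LoG filter | 63 | 9 statistics × 7 sigmas (0.5–3.5 mm) of the Laplacian-of-Gaussian response |
| fractal | 3 | boundary box-counting dimension, intensity (differential box-counting) dimension, lacunarity |
| sigmoid | 6 | mean/SD of amplitude, logistic scale, and baseline of margin profile fits |

Notable definitions:

- **Regions.** The mask is split at `rim_depth_mm` (2 mm, via metric
  erosion) into an inner core and an outer rim. *delta* features are
  statistics of voxelwise differences between seeded random pairings of
  outer and inner voxels (n = min of the two region sizes); *deltaS* uses a
  subsample of half the pairs. Delta statistics cancel global intensity
  shifts by construction and are the main carriers of rim-contrast signal.
- **Discretization.** All texture matrices use equal-width binning into 32
  levels over the in-mask intensity range.
- **GLCM.** The 13 unique 3D directions at distances 1 and 2 voxels,
  symmetrized and normalized; entropies in log2 with the 0·log 0 = 0
  convention; IMC1 = (HXY − HXY1) / max(HX, HY), zero for independent
  marginals and for the degenerate point-mass matrix.
- **GLRLM / GLSZM / GLDM / NGTDM.** Runs along the 13 directions; zones by
  26-connected flood fill; dependence = 1 + equal-level in-mask
  26-neighbours; tone-difference against the 26-neighbourhood mean. The
  GLRLM and GLSZM share a 16-statistic size-matrix summary.
- **LoG.** Separable Gaussian smoothing at sigma in {0.5, 1, ..., 3.5} mm
  (physical units, anisotropy-aware) followed by a discrete Laplacian.
  Scales below half the voxel spacing warn, since the response is then
  dominated by the grid; on the default 1.5 mm grid the 0.5 mm rung of the
  ladder triggers this warning by design, flagging that its response is a
  grid artifact rather than anatomy.
- **Fractal.** Box-counting over dyadic box ladders anchored at the array
  origin (hence not translation-invariant — a documented property, checked
  in the tests); differential box-counting for the intensity surface;
  gliding-box lacunarity anchored at the mask bounding box (translation
  invariant).
- **Sigmoid margin.** `n_profiles = 30` profiles are cast along outward
  surface normals (negative gradient of the smoothed occupancy), sampled by
  trilinear interpolation, and fit with a 4-parameter logistic by
  Levenberg–Marquardt. Features are the across-profile mean and SD of the
  amplitude, logistic scale, and baseline.

**Resolution limit of width recovery.** With the default 1.5 mm voxels and
a 2 mm margin, the true logistic scale is 0.455 mm — under a third of a
voxel — and trilinear sampling biases the fitted scale upward by ≈ 29%.
At a 3 mm margin the bias falls to ≈ 15% and the fit is in the resolvable
regime; the recovery tests therefore use 3 mm. This is measurement physics,
not a fitting defect: amplitude recovery is sub-percent in both regimes.

## 3. Immune profiling

`ssgsea_score()` implements the rank-weighted running-sum score: genes are
ordered by decreasing expression (ties broken by index), in-set genes
accumulate weight `rank^alpha` (alpha = 0.25) normalized by the in-set total,
out-of-set genes accumulate `1/(n − m)`, and the score is the sum of the
running difference. `score_signatures()` scores all 28 sets for all samples
and normalizes by the global range across the whole score matrix. The score
of a sample depends only on that sample's expression ranks, and is invariant
under strictly monotone transforms of the expression values.

`immune_labels()` dichotomizes the th1/th2/ctl scores at **each cohort's own
mean** ("high" iff strictly above): labels are relative to the cohort, so
train and test cohorts get independent cutoffs. `pca_scores()` provides a
PCA view of the signature matrix with `broom::tidy`/`glance` and an
`autoplot` method.

## 4. Modeling and evaluation

### 4.1 Preprocessing

`preprocess_fit()`/`preprocess_apply()` implement a leakage-safe chain:
drop zero-variance features, KNN-impute missing values (k = 5, distance in
z-scored complete features), a maximum-likelihood Yeo–Johnson transform per
feature, then center/scale. All statistics are estimated on the training
portion only and frozen for application to held-out data; inside the
bootstrap the whole chain is refit on every resample.

### 4.2 The classifier roster and complexity ranks

Eight models, each wrapped behind `fit_model()`/`predict_scores()` with
scores oriented so that larger means more likely "high":

1. LDA (closed-form, pooled covariance; falls back to a small ridge with a
   message when the covariance is singular)
2. penalized_DA (covariance shrunk toward its diagonal by `gamma`)
3. penalized_logistic (elastic net via glmnet)
4. sparse_DA (L1-penalized discriminant direction)
5. naive_bayes (Gaussian)
6. CART (rpart)
7. bagged_CART
8. random_forest (ranger)

The ranks encode interpretability: a linear discriminant with five
standardized group means is the preferred end product, echoed by
`lda_group_means()`, which reports the Table-6-style standardized group
means of the retained predictors.

The default predictor panel (`default_predictor_panel()`) is seven features:
total and outer-region skewness, total kurtosis, subsampled-delta variance,
GLCM IMC1 at distance 1, the delta-region mean, and the sigmoid margin
amplitude — the margin/histogram features through which the generator's
coupling acts, plus their paper-analogue companions.

### 4.3 The 0.632 bootstrap

`bootstrap632_evaluate()` draws `B = 25` bootstrap resamples. Per resample:
refit preprocessing, select hyperparameters from a small fixed grid by
out-of-bag AUC, compute apparent (in-bag) and out-of-bag AUC / sensitivity /
specificity (threshold = Youden's J maximizer on the apparent scores), and
combine as `0.368 * apparent + 0.632 * oob`. Reported values are means over
resamples and SDs are across-resample SDs. Resamples whose out-of-bag set
lacks a class are dropped (`B_used`).

**Null calibration.** With no planted coupling (`coupling_beta = 0`,
n = 100, p = 7 predictors, B = 25), the estimator's mean AUC across five
bootstrap seeds measured 0.505–0.592 over cohort seeds — inside the
documented [0.40, 0.60] band but right-shifted from 0.5. That shift is the
known small-sample optimism of the plain 0.632 estimator (the apparent term
is optimistic and is not rescaled as in the 0.632+ variant); it is a
property of the estimator, not a leak in the pipeline.

### 4.4 Selection and reporting

`select_final_model()` keeps every model whose AUC is within one SD (the
best model's SD) of the best AUC and returns the one with the lowest
complexity rank — operationalizing "not significantly better, so take the
simpler model". On the fixture {random forest 0.795 ± 0.108, LDA 0.772,
penalized logistic 0.754} this selects the LDA.

`roc_auc()` computes the exact Mann–Whitney AUC (ties counted half) with a
two-sided Mann–Whitney p-value; `roc_points()`/`plot_roc()` provide the ROC
curves. `evaluate_models()` runs the roster and returns a tibble with
`tidy`/`glance` methods.

## 5. Orchestration and problem sizes

`run_pipeline()` executes simulate → extract → score → train → evaluate
from one config (list or YAML), with per-stage seeds derived from a master
seed, and writes every table as CSV plus a JSON manifest with file
checksums; reruns of the same config are checksum-identical. The default
demo (60 train / 40 test phantoms of 40³ voxels, 28 signatures over 5000
genes, 8 models × 25 resamples) completes in roughly one to two minutes on
one CPU; feature extraction is a few seconds per volume and ssGSEA scoring
is near-instant.

## 6. Limitations

- The phantom is a testing instrument, not a CT simulator: one lesion,
  smooth quasi-ellipsoid geometry, stationary texture, no partial-volume or
  reconstruction effects beyond what trilinear sampling induces.
- Expression is Gaussian noise plus planted set shifts; normalization
  pipelines for real microarray/RNA-seq data are out of scope.
- The delta pairing and sigmoid profile placement are seeded random
  procedures; the corresponding features are deterministic given the seed
  but not invariant to voxel reordering (e.g. rotations), unlike the
  set-statistic histogram features.
- Box-counting dimensions are anchored to the array origin and are
  therefore not strictly translation-invariant; lacunarity is anchored to
  the mask bounding box and is.
- Real-data effect sizes (the paper-scale AUCs) are not reproducible
  without the original images and expression data; the package's claims are
  about internal consistency and recoverability of planted signal.
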