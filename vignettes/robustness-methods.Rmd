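---
title: "Perturbation-based robustness analysis of radiomic features and models"
author: "radrobust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perturbation-based robustness analysis of radiomic features and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radrobust)
```

## The problem

Radiomic models predict clinical outcomes from large panels of quantitative
image features computed inside a tumor segmentation. Many of those features
are not reproducible: small changes in patient positioning, scanner noise, or
the delineated contour change their values substantially. Test-retest scans,
the classical way to measure this, are rarely available, so reliability is
instead estimated by *simulating* acquisition and segmentation variation —
rigid translations and rotations, additive noise fields, and randomized
contours — and treating each simulated perturbation as a "rater" of the same
patient. A feature's robustness is then the one-way random intraclass
correlation of its values across patients (subjects) and perturbations
(raters).

This package implements that pipeline end to end and asks the question the
design exists for: **what happens to a radiomic model when low-robust
features are removed before feature selection?** Three model families are
compared — built from all features with ICC > 0, from "good-robust" features
(ICC > 0.75), and from "excellent-robust" features (ICC > 0.95) — on two
axes:

* **Model robustness**: ICC(1,1) of the model's continuous prediction scores
  across perturbed versions of the test patients.
* **Generalizability**: the train-test AUC difference
  `AUC_test - AUC_train`; values near zero mean the apparent training
  performance transfers.

## The statistic

For an `n x k` ratings matrix (patients by perturbations),

$$\mathrm{ICC}(1,1) = \frac{MS_R - MS_W}{MS_R + (k-1)\, MS_W},$$

where `MS_R` is the between-patient mean square and `MS_W` the within-patient
residual mean square of the one-way random ANOVA. `icc_1_1()` reports the raw
estimate (which can be negative), the mean squares, and an F-based confidence
interval for reporting. Perfect agreement gives 1; pure rater noise gives
values near 0. The `(k-1)` coefficient is the standard single-rater, one-way
form; `feature_icc_table()` applies it per feature, and features whose ICC is
undefined (zero total variance) are flagged and treated as non-robust.

## The pipeline

1. **Preprocessing** (`resample_pair()`, `resegment()`): isotropic
   resampling (default 1 mm; images via cubic-convolution interpolation,
   masks via trilinear interpolation thresholded at 0.5 with exact ties
   resolved by the nearest neighbour — plain thresholding dilates masks by
   about 5% at integer spacing ratios), then soft-tissue re-segmentation to
   the [-150, 180] HU window.
2. **Filter bank** (`filter_bank()`): the original image, Laplacian-of-
   Gaussian images at sigma = 1, 3, 6 mm (scale-normalized, spatial domain),
   and the 8 sub-bands of a single-level stationary coiflet-1 wavelet
   transform (undecimated, so sub-bands keep the image grid).
3. **Features** (`extract_all()`): 3D shape (volume, mesh surface area,
   sphericity, maximum diameter, elongation, flatness), first-order
   statistics, and GLCM / GLRLM / GLSZM texture over every
   (filter image, bin count) pair, with fixed-bin-count discretization
   (default bin counts 50-350). Texture matrices use the 13 unique 3D
   directions at distance 1 (26-connectivity for size zones) and features
   are averaged over directions, following the IBSI definitions.
4. **Perturbations** (`build_perturbation_grid()`, `apply_perturbation()`):
   the default grid is translations 0-3 mm in 0.2 mm steps per axis (4,096
   vectors), rotations -20..20 degrees in 5-degree steps about the SI axis,
   noise levels 0-3, and 30 contour randomizations — 4,423,680 combinations,
   of which a per-patient random subset (60 in the full design) is drawn.
   Mode order: rigid transform, then noise, then contour randomization, so
   the contour constraints are checked on the final mask.
5. **Experiment** (`run_experiment()`): repeated stratified CV (default
   2-fold x 30 repetitions = 60 splits). Per split, feature ICC is computed
   from training-side patients only, features are filtered at each
   threshold, selected by bootstrap-ANOVA frequency ranking (100 balanced
   downsampling iterations, p < 0.1, top 10% of the filtered pool) followed
   by correlation pruning (|r| > 0.6, the pair member with the higher mean
   correlation leaves, at most 10 features), and each classifier is trained
   and evaluated. Paired two-sided t-tests compare each filtered group
   against no filtering across splits; p-values are reported raw, without
   multiplicity correction.

## Tunable parameters that matter

| parameter | default | why |
|---|---|---|
| target spacing | 1 mm isotropic | makes mm equal voxels for LoG sigmas and the Hausdorff constraint |
| re-segmentation window | [-150, 180] HU | soft-tissue range; excludes bone/air from texture |
| bin counts | 50..350 by 50 | fixed-bin-count discretization over the ROI min-max |
| contour constraints | Dice >= 0.75, Hausdorff <= 5 mm | keeps randomized contours within plausible inter-observer variation |
| noise scale `sigma_base` | 10 HU per level | the grid's levels 0-3 are unitless; this sets their physical size |
| DVF smoothness | 5 mm Gaussian | smooth, organ-scale contour deformations |
| perturbation replicates `k` | 20 (configurable to 60) | ICC stabilizes well below 60 raters; runtime scales linearly in k |
| thresholds | 0 / 0.75 / 0.95 | the three model families compared |

## Numerical choices

* **Interpolation.** Images use Keys cubic-convolution (Catmull-Rom), the
  standard interpolating cubic kernel; a true B-spline interpolator would
  need a prefilter pass for no practical gain here. Masks use trilinear
  + 0.5 with nearest-neighbour tie resolution (above).
* **Surface meshes.** Surface area comes from marching tetrahedra (six
  tetrahedra per cell around the main diagonal) on the binary mask
  pre-smoothed with a 0.8-voxel Gaussian and linearly interpolated
  iso-vertices. Without the smoothing, the mesh follows the voxel staircase
  and overestimates a digital sphere's area by more than 20%; with it, a
  20 mm digital sphere gets sphericity 0.99 and a large digital cube 0.82
  (analytic 0.806).
* **Contour randomization** is rejection sampling: 3-channel white noise is
  smoothed, scaled to a jittered target mean surface displacement (default
  2 mm), used to warp the mask, and the result is accepted only if it meets
  both constraints; after `max_attempts` (default 100) the violated
  constraint is reported. Hausdorff is the classical 100th-percentile
  surface distance, no relaxation.
* **Discretization** uses right-inclusive equal-width bins over the ROI
  min-max (the minimum maps to bin 1, a value exactly on a boundary to the
  lower bin); a constant ROI collapses to one bin with a warning.
* **Degenerate inputs.** Empty re-segmented masks flag all intensity and
  texture features as missing rather than erroring; constant features score
  zero selection hits; zero-variance ratings make the ICC an explicit error
  at the single-feature level and a flag at the table level.
* **Determinism.** Every stochastic step derives its stream from a global
  seed and a string tag (FNV-1a), so cohorts, perturbation draws, selections
  and fits are bit-reproducible and per-patient draws are independent of
  patient order.

## Classifiers

Five classifiers sit behind one fitted-predictor contract
(`train_classifier()` / `predict()`): ridge logistic regression (glmnet),
a linear squared-hinge SVC, a k-nearest-neighbour vote, a depth-limited Gini
decision tree, and a one-hidden-layer MLP. The last four are compact
in-package implementations because no suitable packages are available in the
build environment; the analysis treats classifier internals as exchangeable,
and every model exposes continuous scores (never hard labels — ICC on binary
outputs is degenerate). Hyperparameters are tuned by inner stratified CV
maximizing AUC over small documented grids (ridge/SVC strength over 5
log-spaced values, k in 3/5/7/9, depth 2/3/4, hidden units 2/4/8); when the
training fold has fewer than four minority cases, tuning falls back to the
middle grid value.

## What the synthetic data emulates — and what it does not

`generate_phantom_cohort()` builds single ellipsoidal tumor-like objects in
the soft-tissue HU range whose within-mask heterogeneity has a coarse
(6 mm correlation length) and a voxel-scale component, both amplified in
event cases. The coarse component survives mm-scale rigid moves and noise;
the voxel-scale component does not — so outcome signal exists in both robust
and fragile texture, which is precisely the situation in which robustness
filtering has observable consequences.

`generate_feature_table()` skips the image stack and simulates feature
tables with *calibrated* reliability: a feature with target ICC rho is
`subject value + noise` with noise variance `(1 - rho) / rho` against unit
between-subject variance (the class shift of informative features is
absorbed into that unit variance, so the marginal ICC matches the target —
the estimator recovers each tier to within about 0.001 at n = 200, k = 20).
The default `truth_profile()` is calibrated to the real-data regime the
method was developed in: 400 features against ~100 training patients, event
rate 0.2, a robustness histogram with 11% of features above ICC 0.95 and
50% above 0.75 (matching reported survivor fractions), weak outcome signal
(held-out AUC around 0.6-0.7), and heavy-tailed (variance-matched Student-t,
4 df) measurement noise on the fragile tier. The heavy tail is deliberate:
low-robust features in real radiomics are noise-dominated, outlier-prone
measurements, and that is what makes them prone to spurious (type I)
selection — the mechanism behind the generalizability findings.

What the generators do **not** emulate: anatomically realistic CT (organs,
bone, air cavities), multi-lesion patients, scanner-specific noise spectra,
inter-feature correlation structure of real radiomic panels, or batch
effects between cohorts. A green directional test therefore establishes that
the pipeline reproduces the *mechanism* — filtering low-robust features
makes models more robust and less overfit when fragile features carry
spurious or attenuated signal — not that any particular real-data effect
size will be matched.

One subtlety worth knowing: repeated CV inside a single realized cohort is
*cohort-conditionally* biased above 0.5 even under a pure null, because a
chance feature-outcome association in the finite cohort shows up in both
halves of every split. The null-calibration test therefore averages over
independent null cohorts, where the marginal expectation is exactly 0.5.

## Design choices where the design was open

* Noise levels have no stated physical unit; they scale a configurable
  `sigma_base` (default 10 HU).
* The translation grid is taken literally as non-negative shifts (16 values
  per axis, reproducing the printed 4,096 vectors); symmetric negative
  shifts are not added.
* Rotations are about the SI axis through the mask centroid; whether the
  original design rotated about the image center is unstated.
* Noise is added after resampling, and the contour constraint is checked on
  the final (post-rigid) mask; the original ordering is unstated.
* "Top 10%" in selection is computed on the robustness-filtered pool (the
  workflow filters before selection).
* Model robustness uses continuous scores; whether probabilities or labels
  were scored originally is unstated, but ICC on hard labels is degenerate.
* Both modeling modes are exposed: the default models the unperturbed
  table; `average_perturbed = TRUE` models features averaged over
  perturbation replicates.
* mRMR (the selector-bias check) uses |point-biserial correlation| as its
  relevance term so relevance and redundancy share the [0, 1] scale; a raw
  F statistic would make the redundancy penalty vacuous.

## Known limitations

* The extractor is compact and IBSI-faithful but does not reproduce any
  specific 5,000+-feature reference configuration; feature counts are a
  deterministic function of the configuration and are reported, not matched
  to external tools.
* Pure-R volumetric processing caps practical image sizes at desk scale
  (tens of thousands of mask voxels per patient); the analysis scripts and
  acceptance checks scale cohorts and replicate counts down accordingly and
  say so where they do.
* DICOM/RT-STRUCT ingestion is out of scope; volumes are read and written
  as ASCII NRRD.

## A minimal run

```{r example, eval = FALSE}
sf <- generate_feature_table(200, profile = truth_profile(),
                             n_replicates = 20, seed = 1)
ex <- run_experiment(sf, experiment_config(classifiers = "ridge", seed = 1))
print(ex)
ex$comparisons
```

The `analysis/` directory holds the numbered drivers that run the full
study at desk scale (simulation, perturbation + extraction, feature
robustness, modeling experiment) and write their tables under `results/`.
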