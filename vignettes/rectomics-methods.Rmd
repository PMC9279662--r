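---
title: "Radiomics prognostic modeling for rectal cancer: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomics prognostic modeling for rectal cancer: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rectomics` implements a complete multiparametric-MRI radiomics pipeline for
predicting 5-year overall survival (OS) in stage II–III rectal cancer:
image conditioning, a 4,686-slot feature extraction engine, a three-step
feature selection, a sigmoid radiomics score, and a four-model evaluation
suite (TNM staging, clinical, radiomics, combined) with nomogram,
calibration, and Kaplan–Meier outputs. Because no patient imaging is
distributed with the package, a synthetic cohort generator provides data
with the statistical structure the analysis assumes, so that every stage is
testable end to end.

## The statistical model

Each patient contributes eight MRI channels — T1w, T2w, the ADC map, three
post-contrast dynamic phases (L2, L3, L4 at 15/60/120 s), and two
subtraction images (L3−L1, L4−L1) — plus a binary tumor mask. The pipeline
is:

1. **Preprocessing.** Subtraction channels are formed on raw intensities
   (subtracting after normalization would destroy the contrast-uptake
   signal). Each channel is z-score normalized over the whole-volume
   nonzero support (in-tumor statistics stay informative and are captured
   later by the histogram features), resampled to 1 mm isotropic spacing
   (trilinear for intensities, nearest-neighbour for the mask), and the
   mask is eroded by 1 mm with a discretized ball to shed partial-volume
   and contouring-variance voxels.
2. **Feature extraction.** 6 shape descriptors from the mask, then per
   channel 14 histogram features, 7 gray-level run-length (GLRLM) features
   and 44 gray-level co-occurrence (GLCM) features (22 descriptors × 2
   distances, each averaged over the 13 unique 3D directions) on the
   native volume and on each of the 8 sub-bands of a one-level 3D Haar
   wavelet transform: 6 + 8 × (65 + 8 × 65) = 4,686 features.
3. **Selection.** A Spearman redundancy filter (|ρ| > 0.90, greedy in the
   fixed feature order) followed by L1-penalized logistic regression with
   4-fold cross-validation repeated 100 times under the binomial-deviance
   criterion. The selected λ minimizes mean CV deviance subject to fewer
   than 11 retained features (the 10:1 events-per-variable rule for a
   114-patient training cohort); if the unconstrained optimum is too
   large, λ is increased along the path to the first compliant point.
4. **Signature.** `rad_score = sigmoid(intercept + Σ βᵢ · featureᵢ)`.
   Higher scores mean better expected survival. The package also ships a
   fixed reference 8-term signature (intercept −0.664) whose term keys are
   resolved into the extraction layout, so a freshly extracted feature
   vector can be scored directly.
5. **Evaluation.** Four logistic risk models are fit on the primary cohort
   only: stage alone (TNM), a clinical–histological–radiological set, the
   radiomics score alone, and the combined model (score + LNR + surgery +
   yN, the nomogram covariates). Discrimination is summarized by the
   rank-statistic AUC with a class-stratified bootstrap CI and Harrell's
   C-index (identical to AUC for a binary endpoint — asserted, not
   assumed), calibration by risk-decile Hosmer–Lemeshow with the
   accompanying curve, the combined model is re-expressed as a 0–100-point
   nomogram, and patients are stratified at the Youden-optimal score
   cutoff — frozen on the primary cohort before the test cohort is touched
   once — with product-limit curves and the log-rank test.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| gray levels `g` | 64 | fixed-bin-count quantization over the in-ROI min–max range, recomputed per channel and per wavelet sub-band |
| isotropic spacing | 1 mm | common grid for 3D texture offsets |
| erosion margin | 1 mm | boundary pullback against partial-volume voxels |
| GLCM distances | 1, 2 voxels | short-range co-occurrence at the analysis resolution |
| Spearman threshold | 0.90 | redundancy cut, applied greedily in manifest order |
| CV | 4 folds × 100 repeats | deviance averaged over all fold fits per λ |
| feature cap | < 11 | 10:1 rule at n = 114 |
| AUC CI | stratified bootstrap, 2,000 reps | method left open by convention; seeded |
| HL groups | 10 | risk deciles |
| KM cutoff | Youden's J | "cutoff on the ROC curve" made concrete |
| ICC form | ICC(2,1) | two-way random effects, absolute agreement, single rater |

## The synthetic cohort generator

`generate_cohort()` emulates the cohort the analysis assumes rather than
MRI physics. Tumors are ellipsoids (radius 6–9 mm by default, jittered
axes) filled with correlated Gaussian noise; all background voxels are
i.i.d. standard normal. Three planted effects distinguish the non-survivor
group, applied identically in every channel with independent noise:

* `texture_correlation_length` (default 0.5 voxels of extra Gaussian
  smoothing): movable by GLCM/GLRLM features;
* `histogram_skewness_shift` (default 0.4): a standardized log-normal
  intensity component, movable by histogram skewness;
* `mean_intensity_shift` (default 0.2 SD): movable by histogram location
  features.

Clinical covariates are drawn from the OS-group-conditional marginals of
the reference cohort's characteristics table (primary and test columns
pooled), which is what makes the clinical and TNM models weakly prognostic
and reproduces the qualitative AUC ordering combined ≥ radiomics >
clinical > TNM. Stage and clinical nodal status are drawn jointly (stage
II ⇒ cN0), nodal counts are generated consistently with yN and the LNR
identity, and survival months are drawn conditional on the OS label so
that `os_5yr ⇔ survival ≥ 60 months`. Surgery marginals follow the
reference text counts (61/19/14/6%), with the OS-conditional split chosen
to preserve those margins at 75% prevalence while giving LAR the best and
Hartmann's procedure the worst prognosis. The default volume is 24³ voxels
at 1 mm — a deliberately compact phantom geometry that keeps a full cohort
extraction in tens of seconds while leaving room for the 1-mm erosion and
wavelet decomposition.

What the generator does **not** emulate: scanner physics, bias fields,
motion, inter-sequence registration error, non-ellipsoidal morphology, or
any real joint distribution between imaging and clinical covariates.
Passing tests on synthetic cohorts therefore demonstrate that the
pipeline's machinery is correct and that planted signal of the stated kind
is recoverable — not that the published real-cohort performance numbers
are reproduced; those require the original (unreleased) images.

## Numerical choices

* **Quantization**: `level = min(G, ⌊G·(x−min)/(max−min)⌋ + 1)`, constant
  regions map to level 1; invariant to positive affine intensity scaling.
* **Percentiles**: linear interpolation between order statistics (type 7).
* **Skewness/kurtosis**: Fisher g₁ and excess kurtosis; both defined as 0
  for constant samples.
* **z-score**: population SD, so a two-point region {1, 3} maps exactly to
  {−1, +1}; re-application is a no-op.
* **Degenerate textures**: a constant ROI yields maximum probability and
  energy 1; entropy-, contrast-, and correlation-type features 0.
  Directions with no valid voxel pair are excluded from the 13-direction
  average.
* **GLCM information measures**: for the symmetric matrix, HXY1 = HXY2 =
  2·HX exactly; the implementation uses this identity.
* **Wavelet**: order-1 Daubechies (Haar), replicate boundary handling for
  odd axes; decimated coefficients satisfy Parseval on even grids
  (asserted at 1e-8), and sub-bands are replicated back onto the input
  grid so the eroded mask applies.
* **Surface area**: marching tetrahedra with linear interpolation over a
  lightly smoothed (σ = 1 voxel) mask indicator; the enclosed mesh volume
  (divergence theorem) is used in the sphericity/compactness ratios so a
  digitized ball scores ≈ 0.99 and the isoperimetric bound caps the value
  at 1. Masks too small to survive smoothing fall back to the raw binary
  mesh.
* **Convexity**: the fraction of voxel centers inside the convex hull of
  the boundary voxel centers that belong to the mask — exactly 1 for
  digitized convex bodies, computed with an incremental 3D hull.
* **Erosion**: ball structuring element discretized by center distance ≤
  radius; the volume border counts as background; emptying the mask is an
  error.
* **Redundancy filter ties**: deterministic feature order (channel,
  sub-band, family, name, distance) decides which of two correlated
  features survives.
* **λ selection**: minimum-deviance criterion (not 1-SE), with the cap
  rule above.
* **Hosmer–Lemeshow**: χ² against `groups − 2` degrees of freedom, the
  distribution valid for in-sample fitted predictions; duplicate quantile
  bins are merged.
* **Unseen factor levels** at prediction time carry no coefficient and
  fall back to the reference level.

## Design choices where the design was open

* The sequence list names nine channels but the analysis counts eight; the
  default channel set drops L2−L1 and keeps L3−L1 and L4−L1 (the later
  uptake phases carry the contrast dynamics), and the list is
  configurable.
* The reference signature's accompanying feature list and its printed
  formula disagree on two terms; the formula is authoritative and the
  conflict is recorded in the model's metadata note. Its GLCM terms are
  resolved at distance 1, and "LAVA2/LAVA3" resolve to the raw phase
  channels L2/L3.
* "Linear correlation" vs "Spearman test": Spearman is used, being the
  named test.
* Each wavelet sub-band is quantized independently before texture
  analysis, mirroring the per-channel rule.
* Shape features are computed once per patient (implied by the 4,686
  arithmetic), not per channel.
* The 22-descriptor GLCM set (autocorrelation, cluster prominence/shade/
  tendency, contrast, correlation, difference average/entropy/variance,
  dissimilarity, energy, joint entropy, homogeneity, IMC1, IMC2, inverse
  difference, maximum probability, sum average/entropy/variance, variance,
  inverse variance) is fixed so that 22 × 2 distances = 44 and includes
  the two descriptors the reference signature uses.
* Reproducibility analysis emulates a second reader by thresholding a
  softened mask indicator corrupted with smooth random noise; ICC(2,1) per
  feature with the 0.6 pass gate and the five-band interpretation scale.
  Excluding sub-0.6 features before selection is available but off by
  default.
* The primary/test split is an index split at fraction 114/165 (the
  reference design is temporal; synthetic patients are exchangeable).

## Problem sizes used by the test suite and acceptance script

All simulation sizes are package choices balancing statistical
resolution against a desk-scale runtime: the flagship end-to-end run uses
165 patients split 114/51 with the full 100-repeat CV; the replicate
ordering check uses 10 cohorts of 110 patients with 15-repeat CV; the null
control uses 100 patients split evenly; prevalence convergence is checked
on label draws at n = 2,000; texture oracles run on random ROIs up to 16³
voxels. The qualitative conclusions (AUC ordering, null behavior,
calibration) are insensitive to these sizes.

## Known limitations

* Synthetic tumors are ellipsoidal and stationary inside the mask; shape
  features carry essentially no prognostic signal by construction.
* The default planted effects produce stronger discrimination
  (held-out AUC ≈ 1 at n ≈ 100–200) than typical real cohorts; they are
  chosen to make signal recovery unambiguous, not to match a particular
  AUC.
* Deaths after 60 months are not simulated: survivors are censored at last
  follow-up, non-survivors are events. The log-rank test with that coding
  is exact for the generator but simpler than real survival data.
* No 2D extraction mode, no bias-field or registration handling, and no
  claim of IBSI certification for the feature definitions; all conventions
  are pinned by the oracle tests instead.

## A minimal run

```{r, eval = FALSE}
library(rectomics)
report <- run_pipeline(cohort_config(n_patients = 60, seed = 1),
                       selection = selection_config(repeats = 10, seed = 1),
                       split_fraction = 0.7, boot = 200)
glance(report)            # AUC / C-index per model and cohort
tidy(report$signature)    # the fitted signature
plot_model_roc(report)    # four-model ROC overlay
```
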