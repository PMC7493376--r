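---
title: "petrad: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{petrad: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

petrad implements a fully automatic analysis chain for amino-acid PET
studies of brain metastases: quantification, biological-target-volume (BTV)
delineation, radiomics feature extraction, longitudinal change, feature
selection, and discriminant classification. This vignette documents the
models and the design decisions behind each stage, including the choices
made where the underlying methodology is stated only loosely in the
literature, and what the synthetic validation does and does not demonstrate.

## Quantification

Reconstructed PET voxels carry activity concentration in Bq/ml. The
body-weight standardized uptake value is

SUV = activity / (injected dose / body weight),

in g/ml, computed by `to_suv()`. Activity is assumed decay-corrected by the
scanner, the universal convention for reconstructed clinical PET;
`decay_correct()` offers an explicit correction with the carbon-11 half-life
(20.4 min) for raw data. The decay-reference convention is deliberately
exposed as an explicit step rather than guessed. SUL normalization
(`to_sul()`) rescales by lean body mass over total weight, with LBM from the
James (1976) formula — the classical convention in PET quantification:

* male: LBM = 1.10 W − 128 (W/H)²
* female: LBM = 1.07 W − 148 (W/H)² (W in kg, H in cm).

NIfTI-1 is the on-disk format (RNifti); scalar volumes are written float64
so values round-trip exactly, masks as uint8. DICOM series are not parsed —
no DICOM reader is a package dependency — and should be converted upstream.

## Automatic BTV delineation

The segmentation needs no operator input:

1. **Seeding.** The voxel with the highest SUV in the volume (ties broken
   by lowest linear index, so results are reproducible) seeds the first
   lesion.
2. **Region growing.** The 26-connected region of voxels at or above 40% of
   the seed SUV provides a rough lesion estimate. 40%-of-maximum is the
   standard rough PET delineation rule; the region only initializes the
   contour, so its exact level is not critical.
3. **Localized active contour.** On the seed slice, a level set evolves
   under the localized uniform-modelling (local mean-separation) energy:
   each contour point compares the mean SUV of its local interior and
   exterior within a ball (default radius 5 mm, matched to clinical PET
   resolution), with curvature regularization (weight 0.2). Iteration stops
   when fewer than 0.5% of narrow-band pixels change side over 10
   consecutive iterations, or at 300 iterations. The embedding is
   reinitialized to a signed distance every 15 iterations.
4. **Slice propagation and the disease-free stop.** The refined contour,
   dilated by one voxel, initializes the neighbouring slice, superiorly and
   inferiorly, so the contour can locally widen or tighten as the lesion
   cross-section changes. Propagation in a direction stops at a
   *disease-free slice*: the refined contour is empty, covers fewer than
   2 pixels, or its interior mean does not exceed 1.5× the slice background
   (median SUV outside the dilated initialization box). The criterion is
   image-driven; the algorithm has no knowledge of where the tumour ends.
5. **Partial-volume guard.** Scanner blur (PSF ~5 mm FWHM) combined with
   thick slices spills lesion signal into cap slices, where a low wide bump
   survives the local contrast test and inflates the contour. Each refined
   slice is therefore intersected with the background-adaptive isocontour
   at background + 0.4 × (peak − background), where the peak is the mean of
   the 3×3 in-plane patch at the seed (robust to voxel noise). The 0.4
   fraction mirrors the delineation convention of step 2 and was calibrated
   on blurred-sphere phantoms (radii 6–15 mm, 5 mm FWHM), where it yields
   Dice 0.97–0.99 against the pre-blur truth; it is configurable
   (`pvc_fraction`, 0 disables).
6. **Multi-lesion loop.** After each lesion, its dilated BTV, its
   region-growing basin, and its contiguous supra-threshold component are
   excluded from the seed search (SUVs are never altered), and the next
   maximum is sought. The loop ends when the candidate seed falls below
   2 g/ml. The basin exclusions matter: without them, the blur shoulder of
   a segmented lesion (2–3 g/ml, connected to it) would re-seed as a
   false-positive lesion — precisely the failure the multiple-lesion
   warning exists for. A warning is emitted whenever more than one lesion
   is returned.

Every step is deterministic; identical inputs give identical masks. Each
BTV is a single 26-connected component containing its seed; the first BTV
contains the global maximum; BTVs are pairwise disjoint.

## Radiomics features (108 per lesion)

In-mask SUVs are quantized to 64 equal-width grey levels between the lesion
minimum and maximum (maximum maps to level 64; a constant lesion maps to
level 1). Texture matrices are built in 3D with 26-voxel connectivity and
accumulated over the 13 unique direction offsets before normalization;
entropies use log2. The nine families and their index counts:

| family | indices |
|---|---|
| co-occurrence (Haralick forms) | 7 |
| voxel-alignment (run length) | 11 |
| neighbourhood intensity difference (Amadasun–King) | 5 |
| intensity size-zone | 11 |
| normalized co-occurrence (row-conditional) | 6 |
| texture spectrum (He–Wang units, in-plane 3×3) | 2 |
| texture feature coding | 4 |
| texture-feature-coding co-occurrence | 8 |
| neighbourhood grey-level dependence | 5 |

plus 49 first-order SUV indices. Definitional choices worth recording:

* **Runs** are maximal collinear same-level in-mask sequences; out-of-mask
  voxels break runs. Run percentage is normalized by (in-mask voxels ×
  directions) so the pooled value stays in (0, 1].
* **Zones** are 26-connected same-level components.
* **NGTDM** uses 26-neighbour in-mask means, an epsilon of 1e-6 in the
  coarseness denominator and a 1e6 cap so constant lesions stay finite;
  busyness and strength of single-level lesions are defined 0.
* **Texture spectrum** follows the original 2D 3×3 definition (all other
  families are 3D); units exist only where the full 3×3 in-plane
  neighbourhood lies in the mask, so pencil-thin lesions yield NaN with a
  logged reason. Black-white symmetry compares the spectrum with its
  intensity-inverted mirror.
* **Texture feature coding**: per axis, the two opposite-neighbour level
  differences classify a voxel as flat (0), monotone/step (1) or
  crest/valley (2); the voxel code is the class sum over the 13 axes. The
  coding uses level differences only, so it is invariant under uniform
  level shifts. The co-occurrence family on the coded map reports 8
  indices; the published feature list names nine quantities under an
  "8 features" heading, and the registry resolves the discrepancy by
  dropping the redundant code-similarity entry so the total stays 108.
* **First-order statistics** use population moments; skewness and kurtosis
  (plain, not excess) also come in bias-corrected forms, and both are
  defined 0 for zero-variance lesions so constant phantoms remain usable.
* **Surface area** is estimated by the coarea formula on the indicator
  smoothed with an isotropic 1.5 mm Gaussian — the sigma balances
  staircase error against curvature flattening and keeps voxelized spheres
  of radius ≥ 8 mm within a few percent, where raw face counting
  overestimates by ~50%. Asphericity A = (S³/36πV²)^{1/3} − 1 is reported
  for three surface estimates (coarea, exposed-face, surface-voxel count);
  the products use the coarea variant. Surface-restricted SUV statistics
  use four surface definitions: boundary voxels by 6-, 18- and
  26-connectivity, and the exterior face-adjacent shell. NSR is the
  coefficient of variation (SD/mean) of surface SUVs.
* **SULpeak** is the maximal mean SUL in a 1 ml sphere centred on any
  in-mask voxel; the sphere may extend outside the BTV (PERCIST
  convention). It is NaN, with a logged reason, when no SUL volume is
  supplied.
* No resampling to isotropic voxels is performed; matrices see the grid as
  acquired, and anisotropy (e.g. 1.17 × 1.17 × 3.27 mm) is part of the
  texture signal, as in the toolchain this mirrors.

`extract_features()` always returns exactly 108 named values in a fixed
registry order (`feature_registry()`), with NaNs only for degenerate
lesions or missing SUL input, each with a recorded reason.

## Longitudinal change

`delta_percent()` computes, per feature, 100 × (follow-up − baseline) /
baseline. Zero baselines make the ratio undefined; those features are NaN
with their names logged, and downstream selection drops features with more
than 20% missing values.

## Feature reduction and selection

Two steps against a binary outcome (responder = 1):

1. **Correlation de-duplication.** Iterating over features in registry
   order, each not-yet-deleted feature forms a group with all features
   whose pairwise |Pearson r| exceeds 0.9; the group member with the
   largest |point-biserial| correlation with the outcome is kept (ties go
   to the earlier column) and the rest are deleted; sweeps repeat until
   stable, so survivors are pairwise decorrelated below 0.9.
2. **Threshold selection.** Point-biserial coefficients are recomputed for
   the survivors and features with |r_pb| > 0.25 are selected; each
   selected feature's univariate ROC AUC with a DeLong 95% CI is reported.

Absolute correlations are used for both thresholds: anti-correlated
duplicates are still duplicates, and inversely associated features are
still informative. The point-biserial coefficient is computed as the
Pearson correlation with the 0/1 coding — they are identical by
definition. Constant features and features with too many missing values
are dropped up front and recorded in the audit trail, which also lists
every eliminated feature and the group member that displaced it.

## Discriminant classification

`cross_validate()` runs stratified k-fold cross-validation (default k = 5;
fold class proportions within one member of the cohort proportions;
deterministic given the seed). The classifier is a linear discriminant with
pooled within-class covariance and empirical priors (MASS::lda); when the
pooled covariance is singular — unavoidable when all 108 features are used
on small cohorts — a ridge-regularized pooled-covariance Gaussian
discriminant (diagonal load 1e-6 × trace/p) takes over and is flagged in
the model object. Out-of-fold posterior probabilities are pooled into a
single confusion matrix at the 0.5 threshold, from which sensitivity,
specificity, precision, negative predictive value, error and accuracy are
reported in percent (error ≡ 100 − accuracy by construction), and into a
single ROC of the combined predicted probability with its AUC and DeLong
95% CI. Pooling, rather than fold-averaging, is the aggregation that
yields one ROC per experiment; per-fold metrics are also kept in the
report. `compare_feature_sets()` applies identical folds to two feature
sets for selected-versus-all contrasts.

## Synthetic data: what it emulates, and what it does not

`make_pet_phantom()` emulates brain amino-acid PET: uniform low background
(default 0.5 g/ml), one or more quasi-spherical lesions with uptake in the
clinically typical 3–10 g/ml range, Gaussian PSF blur (5 mm FWHM in the
validation suite), and Gaussian or scaled-Poisson voxel noise, on the
clinical anisotropic grid (1.17 × 1.17 × 3.27 mm) so slice-thickness
effects are exercised. Lesions are rasterized with 3× supersampling for
partial-volume edges; ground truth is the pre-blur indicator (fill
fraction ≥ 0.5) — accuracy is judged against the biological extent, not
the blurred image. It does *not* simulate scatter, randoms, reconstruction
artifacts, anatomical background structure, or infiltrative lesion shapes;
a Dice of 0.97 on these phantoms therefore bounds geometric fidelity of
the contour machinery, not clinical performance.

`make_feature_cohort()` generates class-conditional Gaussian feature tables
with planted standardized mean shifts and latent-factor correlated blocks,
for validating the selection and classification stages against known
ground truth. Real radiomics features are neither Gaussian nor
block-structured; the cohorts validate the statistics, not the biology.

Validation problem sizes (chosen to keep the full suite and the
acceptance script in the minutes range): blurred-sphere phantoms on
64 × 64 × 40 grids at radii 6–15 mm; selection recovery over 20 replicates
of 60-observation, 108-feature cohorts with 3 informative features at
effect size 1.5; a 200-shuffle permutation null for the cross-validated
AUC.

## Numerical conventions and degenerate inputs

* Quantization of a constant lesion: all voxels level 1.
* Single-voxel lesions: no voxel pairs — co-occurrence-type families are
  NaN with logged reasons; dependence counts are 0 (small-number emphasis
  1).
* GLCM correlation with a zero-variance marginal is defined 0.
* The level-set narrow band (half-width 2 px) is re-anchored by distance
  reinitialization if the contour drifts out of it; a vanished contour
  returns an empty mask, which the stopping criterion interprets.
* All randomness (phantoms, cohorts, fold assignment) flows from explicit
  seeds; there is no hidden RNG state.

## Known limitations

* DICOM series must be converted to NIfTI upstream.
* The disease-free criterion and partial-volume guard were designed for
  hyperintense lesions on quiet backgrounds (the amino-acid-tracer brain
  setting); organs with high physiological uptake would need different
  background estimation.
* The coarea surface estimator is biased low for lesions only 2–3 slices
  thick (curvature comparable to the smoothing scale).
* Texture-feature-coding definitions follow this package's documented
  coding; other toolboxes' TFC numbers are not directly comparable.
* Lesion-scale grids are assumed; the pure-R connected-component and
  level-set code targets fields of view of tens of voxels per axis, not
  whole-body volumes.
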