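# petrad

Fully automatic PET biological-target-volume (BTV) segmentation and
radiomics for brain metastases, in R.

Amino-acid PET (e.g. ¹¹C-methionine) shows brain metastases as hyperintense
lesions on a quiet background, which makes fully automatic delineation
feasible — and delineation is the reproducibility bottleneck of PET
radiomics: manual contours are operator-dependent, and every downstream
feature inherits that variability. petrad implements the whole chain for
nuclear-medicine and radiomics researchers:

* **Quantification** — body-weight SUV (g/ml) from activity volumes,
  SUL via the James lean-body-mass formula; NIfTI I/O.
* **Automatic segmentation** — seed at the global SUV maximum, region
  growing at 40% of the seed for a rough ROI, slice-wise localized
  region-based active contour (level set comparing local interior/exterior
  mean SUV within a 5 mm ball, curvature-regularized), slice propagation
  with an image-driven disease-free stopping criterion, and an iterative
  multi-lesion loop that stops when the candidate seed falls below
  2 g/ml (with a multiple-lesion warning).
* **Radiomics** — exactly 108 features per lesion: 49 first-order SUV
  indices (including TLG, SULpeak, surface area, asphericity and
  surface-restricted statistics) and 59 texture features from 9 matrix
  families (co-occurrence, run length, NGTDM, size-zone, normalized
  co-occurrence, texture spectrum, texture feature coding and its
  co-occurrence, grey-level dependence), built on a 64-level quantized 3D
  grid with 26-voxel connectivity.
* **Longitudinal change** — per-feature Δ% = 100 × (follow-up − baseline) /
  baseline.
* **Feature selection** — correlation de-duplication (|r| > 0.9 groups keep
  the member with the best point-biserial correlation against the outcome)
  followed by |r_pb| > 0.25 thresholding with per-feature AUC + DeLong 95%
  CI.
* **Classification** — linear discriminant under stratified 5-fold
  cross-validation; pooled sensitivity/specificity/precision/NPV/error/
  accuracy and the ROC of the combined predicted probability.
* **Synthetic phantoms** — blurred-sphere PET phantoms with ground-truth
  masks and labelled feature cohorts with planted effects, used by the test
  suite to validate every stage.

## Worked example

```r
library(petrad)

# a two-lesion blurred noisy phantom on the clinical anisotropic grid
ph <- make_pet_phantom(
  shape = c(64, 64, 40), spacing = c(1.17, 1.17, 3.27),
  background_suv = 0.5,
  lesions = list(phantom_lesion(c(22, 22, 40), radius_mm = 8, peak_suv = 8),
                 phantom_lesion(c(52, 50, 75), radius_mm = 6, peak_suv = 5)),
  psf_fwhm_mm = 5, noise = list(type = "gaussian", sd = 0.2), seed = 42)

ls <- segment_all(ph$volume)       # fully automatic, no seeds supplied
#> Warning: multiple lesions detected (2); check for false positives
ls
#> <lesion_set> 2 lesion(s)
#>   lesion 1: SUVmax 8.24 g/ml, 2.02 ml
#>   lesion 2: SUVmax 4.69 g/ml, 0.94 ml

dice_coefficient(ls$masks[[1]], ph$masks[[1]])   # vs pre-blur ground truth
#> [1] 0.9559613

fv <- extract_features(ph$volume, ls$masks[[1]])
round(fv[c("suv_max", "suv_mean", "tumor_volume_ml", "tlg",
           "asphericity_1", "cooc_entropy",
           "valign_low_intensity_run_emphasis", "nid_complexity")], 4)
#>            suv_max           suv_mean    tumor_volume_ml                tlg
#>             8.2383             5.7395             2.0188            11.5870
#>      asphericity_1       cooc_entropy
#>            -0.0265            11.1684
#> valign_low_intensity_run_emphasis     nid_complexity
#>             0.0274         15598.0264
```

The first lesion is recovered at Dice 0.96 against the pre-blur analytic
sphere; its SUVmax (8.24) slightly exceeds the simulated 8 g/ml peak because
of voxel noise, the 2.02 ml metabolic volume is close to the 2.14 ml
analytic sphere volume, TLG = mean SUV × volume, and asphericity ≈ 0 says
the recovered shape is spherical. Feature tables for a cohort then flow into
`select_features()` and `cross_validate()`:

```r
tab <- make_feature_cohort(n_per_class = 30, n_features = 108,
                           informative = c(10, 55, 101),
                           effect_size = 1.5, seed = 1)
sel <- select_features(tab)
rep <- cross_validate(tab, sel$selected, k = 5, seed = 1)
rep$metrics
```

A command-line front end with `phantom`, `segment`, `extract`, `delta`,
`select`, `classify` and `run` subcommands is installed under
`inst/cli/petrad` (run `Rscript <path>/cli/petrad segment --help`).

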