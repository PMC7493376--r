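Package: petrad
Title: Fully Automatic PET Biological Target Volume Segmentation and Radiomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A fully automatic pipeline for amino-acid PET studies of brain
    metastases: SUV/SUL quantification, automatic biological-target-volume
    (BTV) delineation by global-maximum seeding, region growing and slice-wise
    localized active-contour refinement with a disease-free-slice stopping
    rule, extraction of 108 radiomics features per lesion (49 first-order SUV
    indices and 59 texture features from 9 grey-level matrix families on a
    64-level quantized grid), longitudinal per-feature percent change,
    two-step feature reduction (correlation de-duplication plus point-biserial
    thresholding with per-feature AUC), and linear discriminant classification
    under stratified k-fold cross-validation. Includes synthetic PET phantom
    and feature-cohort generators with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    EBImage,
    igraph,
    MASS,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
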