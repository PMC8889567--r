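Package: dosiomicsRP
Title: Dosiomic and Radiomic Modeling of Radiation Pneumonitis Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling radiation pneumonitis (RP) risk after thoracic
    radiotherapy from three-dimensional dose distributions and planning CT
    images. Accumulates per-fraction voxel doses into equivalent dose in
    2-Gy fractions (EQD2) under the linear-quadratic model, extracts
    dose-volume histogram (DVH) metrics together with dosiomic and radiomic
    first-order and texture features (GLCM, GLRLM, GLSZM, NGTDM) from lung
    regions of interest, and evaluates L2-regularized logistic risk models
    with nested Monte-Carlo cross-validation, SMOTE class balancing, and
    cross-cohort transfer of selected features. Ships a synthetic thorax
    phantom cohort generator with planted dose and texture effects so the
    whole pipeline is testable without protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
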