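Package: pzgrade
Title: Texture Radiomics and Multi-Site Classification of Peripheral Zone
    Prostate Cancer Aggressiveness
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative assessment of peripheral zone prostate cancer
    aggressiveness from T2-weighted MRI and diffusion-weighted imaging.
    Implements dual-reference pseudo-T2 intensity normalization, voxel
    outlier exclusion, monoexponential apparent diffusion coefficient
    mapping from multi-b diffusion series, fixed-bin-number quantization
    with per-slice directional grey level co-occurrence and run length
    matrices and their IBSI-style features aggregated by the 2D-average
    rule, first-order histogram features, grade-group association
    statistics (Spearman, Mann-Whitney, Benjamini-Hochberg, two-way
    ANOVA site screen), and a hold-one-institution-out linear support
    vector machine evaluation with patient-grouped stratified inner
    cross-validation, recursive feature elimination, Youden threshold
    transfer, DeLong AUC inference and paired across-site testing.
    Includes a multi-site synthetic cohort generator that emulates the
    statistical structure of a multicenter prostate MRI study so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    e1071,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
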