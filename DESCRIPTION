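Package: nwuct
Title: Automated Net Water Uptake from Non-Contrast Head CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fully automated computation of net water uptake (NWU), a
    quantitative ischemic-edema biomarker, from non-contrast head CT.
    Implements the preprocessing chain (field-of-view selection, voxel
    smoothing, skull stripping, affine registration to a brain atlas),
    atlas-space segmentation into the ten anterior-circulation ASPECTS
    regions, bilateral density comparison under a 20-50 Hounsfield-unit
    window, per-region and averaged NWU, and the outcome-model evaluation
    statistics used to benchmark the biomarker (logistic regression fit
    by iteratively reweighted least squares, stratified train/test
    splitting, AUROC, the DeLong paired test, Fisher exact and Wilcoxon
    rank-sum tests). A synthetic head phantom and cohort simulator with
    known ground truth make every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    stats,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
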