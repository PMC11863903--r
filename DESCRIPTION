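Package: habrad
Title: Habitat-Subregion Radiomics for Lymph Node Metastasis Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dual-phase CT tumor habitat analysis: cohort-pooled K-means
    clustering of arterial/venous voxel intensities into habitat subregions
    with Calinski-Harabasz selection of the cluster count, IBSI-style
    radiomics feature extraction (first-order, shape, gray-level
    co-occurrence texture, with Laplacian-of-Gaussian, Haar wavelet and
    square-root filtered variants) from the venous phase, a Spearman
    redundancy filter plus LASSO-logistic radiomic signature, repeated
    stratified train/test evaluation with fused habitat models, ROC/DeLong,
    calibration (Hosmer-Lemeshow), decision-curve analysis, and
    Kaplan-Meier/log-rank survival statistics. Includes a synthetic
    dual-phase phantom generator with planted habitat structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    survival,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    glmnet,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
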