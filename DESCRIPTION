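Package: readiff
Title: Radiomics-Based Prediction of Mammography Reader Difficulty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model which screening mammography cases a cohort of
    readers will find difficult. Generates synthetic high-density breast-like
    image cohorts with simulated reader panels, segments the breast and
    removes the pectoral muscle on MLO views, delineates square, retroareolar
    and whole-breast regions of interest, extracts a 203-feature radiomic
    bank (histogram, GLCM, GLRLM, GLSM, GLDS, NGTDM, SFM, Laws, fractal,
    Gabor, RFS/MR8 and Fourier families), converts reader responses into
    per-case error proportions and easy/median/difficult labels, trains
    nested cross-validated random forests with embedded feature selection
    and maximum-probability view fusion, and evaluates models with ROC
    statistics (stratified-bootstrap confidence intervals, unpaired
    bootstrap AUC comparison and DeLong's paired test).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    ranger,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
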