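Package: blastometry
Title: Morphometric Blastocyst Assessment and Pregnancy-Outcome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts a 24-element micrometre-calibrated morphometric feature
    vector (region geometry, intensity statistics, local-entropy texture and
    Canny edge metrics) from single blastocyst micrographs with manually
    annotated zona pellucida, trophectoderm and inner-area regions; reduces
    the features by standardized PCA with a 99 percent cumulative-variance
    selection rule; appends patient age; and predicts the b-hCG pregnancy-test
    outcome with five classical classifiers under stratified 10-fold
    cross-validation, including a label-permutation over-fitting control.
    A phantom-image generator produces synthetic cohorts with ground-truth
    region masks so the full pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    png,
    tiff,
    jsonlite,
    e1071,
    randomForest,
    rpart,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), pROC, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
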