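Package: canospad
Title: Shade-Aware SPAD Estimation from RGB and Multispectral Canopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nondestructive estimation of relative chlorophyll content (SPAD)
    of tree seedlings from downward-looking canopy images taken under
    different shade levels. Provides a synthetic scene generator with known
    ground truth, index-based gray conversion with Kapur maximum-entropy
    segmentation, white-plate-corrected extraction of ten RGB and ten
    multispectral vegetation indices, multicollinearity-aware feature
    screening (Pearson significance pre-filter, variance inflation factors,
    Lasso with cross-validated penalty), shade-aware regression models
    (ordinary least squares with shade dummy variables, a random-intercept
    mixed model fitted by REML, random forest, RBF support vector
    regression), and an evaluation protocol based on a 3:1 modeling/test
    split with R-squared, RMSE and MAPE.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    tiff,
    jsonlite,
    randomForest,
    e1071,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    lme4,
    optparse
Config/testthat/edition: 3
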