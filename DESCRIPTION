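Package: firescape
Title: Seasonal Wildfire Susceptibility and Focal-Species Habitat Overlap
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A tested pipeline from occurrence points and environmental raster
    stacks to seasonal wildfire-risk maps, species habitat-suitability maps,
    and their overlap. Implements distance-based occurrence thinning, pairwise
    correlation screening of covariates, moving-window landscape diversity,
    two-step pseudo-absence selection gated by presence-only models (climatic
    envelope, Gower-similarity domain, one-class support vector machine),
    AUC-weighted multi-learner classifier ensembles, true-skill-statistic
    thresholding of probability maps, normalized between-season change
    surfaces, and GAP overlap analysis with square-kilometre area accounting.
    Ships a synthetic-landscape generator with known ground truth so the whole
    workflow is reproducible without proprietary satellite inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    mgcv,
    nnet,
    purrr,
    randomForest,
    rlang,
    rpart,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
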