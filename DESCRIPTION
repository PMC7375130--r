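Package: taskbbs
Title: Brain Basis Set Prediction of General Cognitive Ability from Task Contrast Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts a general cognitive ability (GCA) factor from task-fMRI
    contrast maps with Brain Basis Set (BBS) modeling: a bifactor factor model
    of a ten-test behavioral battery with Schmid-Leiman transformation and
    regression factor scoring, principal-component brain features, covariate
    adjustment inside family-aware ten-fold cross-validation, Freedman-Lane
    permutation inference, Levina-Bickel intrinsic dimensionality estimation,
    consensus predictive maps, a simplified resting-state connectome
    comparator, and a network-demand meta-analysis relating frontoparietal
    and default-mode activation to prediction accuracy. Includes a seeded
    synthetic-cohort generator emulating the statistical structure of
    family-clustered neuroimaging studies so the full pipeline is testable
    without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    signal,
    MASS,
    RNifti,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    readr
Config/testthat/edition: 3
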