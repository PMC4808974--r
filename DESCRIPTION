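Package: greenbirth
Title: Residential Greenness and Birth Outcomes with Propensity-Score
    Restriction to Common Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying residential greenness (satellite
    NDVI) and perinatal outcomes across heterogeneous community types.
    Provides a synthetic-data generator with known ground-truth effects and a
    structural-confounding regime; buffer-based NDVI exposure assessment with
    season windows and community-specific tertiles; derived covariates
    (z-score composite indices, inverse-squared-distance animal-feeding
    operation exposure, well counts, road distance); outcome derivation
    including an internal small-for-gestational-age growth reference;
    stacked-ensemble (super learner) propensity scores; percentile trimming
    to the region of common support; and community-stratified effect
    estimation with cluster-robust standard errors, likelihood-ratio-guided
    interaction selection, residual semivariogram diagnostics, and
    sensitivity analyses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    splines,
    glmnet,
    xgboost,
    sandwich,
    lmtest,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
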