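Package: pm25ekc
Title: Panel Econometrics, Ensemble Learning and Environmental Kuznets
    Curves for PM2.5 Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid analysis pipeline for premature mortality attributable
    to fine particulate matter (PM2.5) in country-year panels. Six panel
    econometric estimators (pooled OLS, one- and two-way fixed effects,
    random effects, instrumental-variable two-stage least squares) are
    harmonized with six tree-ensemble regressors through emulated feature
    importances, aggregated by a custom stacking blender into a single
    feature-weight vector. That vector drives importance-weighted
    unsupervised learning (affinity-propagation clustering, six
    dimensionality-reduction methods, predictive manifolds) and
    PCA-decomposed environmental Kuznets curves. A synthetic-panel
    generator with latent economic and health factors, an endogenous
    welfare variable and LOESS-plus-spline imputation makes every stage
    testable without the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    randomForest,
    ranger,
    rpart,
    xgboost,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
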