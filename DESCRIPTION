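Package: vesselmorph
Title: Intracranial Vessel Morphometry and Regression-Based Age Prediction
Version: 0.1.0
Authors@R:
    person("Vesselmorph", "Developers", email = "vesselmorph@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the geometry of intracranial arteries in 3D
    angiography volumes and relating it to subject age. Provides seeded
    region-growing segmentation, 3D topological skeletonization, Dijkstra
    centerline extraction between annotated endpoints, spline smoothing and
    uniform arc-length resampling, six tortuosity descriptors (curve length,
    Euclidean length, relative length, sum of angle metrics, product of angle
    distance, triangular index) and seven distance-transform diameter
    statistics per vessel segment, cohort table assembly with exclusion logic,
    and six regression families (random forest, linear, AdaBoost, gradient
    boosting, Bayesian ridge and regularized gradient-boosted trees) evaluated
    by four-fold cross-validation with Pearson r, RMSE, MAPE and R-squared.
    A synthetic vascular phantom generator (parametric curves, volumetric tube
    phantoms, tabular cohorts) provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    withr,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
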