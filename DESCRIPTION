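Package: coastnest
Title: Coastal Indicators, Self-Organizing Map Clustering, and Sea Turtle
    Nesting Suitability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for explaining the distribution of sea turtle
    nesting from regional coastal indicators. Builds a hexagonal coastal-region
    grid ("Coastgons") from ~1-km shoreline transects, derives 22 hydrodynamic,
    atmospheric, geophysical, habitat and human indicators per region from
    environmental time-series nodes and habitat polygons, screens indicators by
    random-forest feature importance with 4-fold cross-validation, clusters
    regions with a percentile-scaled, maximum-dissimilarity-initialized
    self-organizing map, correlates cluster composition with nesting occupancy,
    and classifies regions as observed / potentially suitable / unsuitable with
    regional summary statistics and Kolmogorov-Smirnov comparisons. Includes a
    synthetic-data generator with planted indicator-nesting relationships so
    every stage is testable without external global datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    mgcv,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
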