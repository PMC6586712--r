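Package: nnpi
Title: Nonnative Plant Indicator Metrics and Design-Based Wetland Survey Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes per-site nonnative vegetation metrics (relative cover,
    richness, relative frequency), classifies wetland sites into stressor-level
    categories via a threshold decision matrix with a max-filter rule, and
    performs design-based population inference for probability surveys:
    Horvitz-Thompson weighted area extent by category, population-weighted
    means with local-neighborhood or with-replacement variance estimates, and
    signal-to-noise repeatability from revisit sites. Also provides a composite
    site-disturbance index from eight standardized sub-indices, a
    class-balanced random-forest exploration of stressor-status predictors,
    and a synthetic survey-data generator so the whole pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
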