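Package: locoeff
Title: Locomotor Efficiency and Training-Load Readiness Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Residual-based monitoring of neuromuscular readiness in team-sport
    athletes from GPS/accelerometer external-load data. Fits a pluggable
    regression model (random-forest-style ensemble or linear model) predicting
    session PlayerLoad from locomotor metrics, derives the Locomotor Efficiency
    Index (LEI) as the individually standardized predicted-minus-actual
    residual, classifies weekly readiness states and week-to-week load
    fluctuations, and estimates the effect of load manipulation strategies on
    week-to-week LEI change with player-level random-intercept mixed models.
    Includes a longitudinal squad simulator with latent impulse-response
    fatigue dynamics for validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    nlme,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
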