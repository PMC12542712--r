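Package: districtsae
Title: Small-Area Estimation of District Disease Prevalence from Cluster
    Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Small-area estimation of district-level hypertension and
    diabetes prevalence from two-stage cluster survey microdata.
    Classifies outcomes from blood-pressure and random-glucose readings
    using WHO cutoffs, fits a four-level (individual / cluster / district
    / state) random-intercept Bayesian logistic model by exact Gibbs
    sampling with Polya-Gamma data augmentation, turns posterior-mean
    (precision-weighted) cluster predictions into district prevalence
    estimates, and compares estimates across survey waves (change bands,
    quadrant counts, cross-outcome correlation).  Includes a calibrated
    synthetic two-wave survey generator with known variance components
    for validation without restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
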