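Package: divebudget
Title: Behavioral States and Time-Energy Budgets from Biologging Tag Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for high-resolution biologging (DTAG-style)
    deployments on small cetaceans: derives kinematic series (minimum specific
    acceleration, pitch, roll) from calibrated depth and triaxial acceleration,
    detects respirations from the depth trace and echolocation buzzes from
    click trains, separates dives from near-surface apneas with a Gaussian
    multivariate mixture, classifies dives into behavioral states with a mixed
    hidden Markov model (discrete random-effect transition contexts, mixed
    Gaussian/beta/Bernoulli emissions, multi-restart maximum likelihood, AIC
    selection), and converts states and detections into activity-specific field
    metabolic rates, foraging efficiency and cumulative energy balance. A
    synthetic tag-data generator with full ground truth supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    mclust,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
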