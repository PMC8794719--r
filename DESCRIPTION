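Package: grousedemog
Title: Post-Wildfire Demographic Analysis of Greater Sage-Grouse
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Vital-rate estimation and stochastic matrix-model analysis for a
    greater sage-grouse (Centrocercus urophasianus) population recovering from
    a mega-wildfire. Provides closed-form estimators for nest initiation,
    clutch size, hatchability and derived juvenile survival; a known-fate
    survival likelihood with staggered entry, censoring, AICc model ranking
    and model averaging; a latent-state brood-count model for chick survival
    with imperfect detection; a two-age female pre-birth-pulse projection
    matrix with parametric-bootstrap confidence intervals on the finite rate
    of population change; and a life-table response experiment decomposing
    variation in population growth into vital-rate contributions. A synthetic
    data generator emulates the field study's encounter-history processes so
    every estimation stage is testable without the original telemetry data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
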