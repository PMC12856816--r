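Package: tenureplan
Title: Latent Extinction Risk and Land-Tenure-Aware Reserve Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links comparative extinction-risk modelling to systematic
    conservation planning across a multi-tenure landscape. Fits generalized
    least squares models of ordinal threat status with combined phylogenetic
    and spatial covariance, finds a minimum adequate model by an AICc-guided
    stepwise search, and computes per-species latent extinction risk averaged
    over a sample of phylogenies. Projects current and latent risk onto an
    analysis grid, tessellates a region into hexagonal planning units with
    tenure classes and proxy costs, builds representation targets, and solves
    the minimum-set reserve-selection problem exactly by branch and bound
    under alternative tenure objectives. A synthetic-data generator with known
    ground truth (phylogenies, traits, ranges, environment, tenure, threat
    statuses) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    jsonlite,
    yaml,
    sp,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
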