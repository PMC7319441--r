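Package: cladoclim
Title: Disparity, Diversification and Paleoclimate Linkage on Time-Calibrated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools linking body-size disparification and net diversification of
    a clade to paleoclimate change on ultrametric, time-calibrated phylogenies.
    Implements disparity-through-time (DTT) curves with Brownian-motion null
    envelopes, the morphological disparity index (MDI) and per-node disparity
    deviations; Pagel's lambda phylogenetic-signal estimation with per-tip
    measurement error; net diversification rate-through-time computed from
    rate-shift event configurations (the posterior "event data" dialect);
    generalized least squares regression with continuous-time CAR(1)
    autocorrelation, AIC model selection with Akaike weights, likelihood-ratio
    pseudo-R-squared and standardized coefficients; staged Pearson
    correlations; and seeded synthetic-data generators (birth-death
    chronograms, lambda-scaled Brownian traits, event configurations,
    autocorrelated climate series) so the whole pipeline is testable with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme
Config/testthat/edition: 3
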