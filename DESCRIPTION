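Package: dqihld
Title: Oral Drug Suitability Parameters from a Three-Compartment
    Pharmacokinetic Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates repeat oral dosing of small-molecule drugs with a
    minimal three-compartment pharmacokinetic model (a saturable,
    time-limited intestinal absorption compartment feeding a classic
    two-compartment disposition model) and derives two oral drug
    suitability parameters from the resulting log-log dose-exposure
    curves: the dose-quantity intercept (DQI) and the highest linear dose
    (HLD).  Includes Henderson-Hasselbalch ionisation handling, pH
    correction of aqueous solubility, Caco-2 to human jejunal
    permeability scaling, hepatic first-pass estimation, five
    distribution-kinetics scenarios per compound, Gaussian input-error
    ensembles on volume of distribution and clearance, and polygon
    analytics (area, centroid, second moments of area) of the resulting
    DQI-HLD vertex clouds.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
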