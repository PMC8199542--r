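Package: copmat
Title: Center-of-Pressure Measurement and Agreement Analysis for Resistive Pressure-Sensitive Mats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Recovers center-of-pressure (CoP) trajectories from low-cost
    resistive pressure-sensitive sensor mats and evaluates their agreement
    with a reference force platform. Implements inversion of the row-column
    voltage-divider readout circuit, elimination of resistor-network crosstalk
    (the "ghost effect") by nodal-analysis inversion of the measured
    equivalent-conductance map, exact deconvolution of the first-order sensor
    time response, postural sway statistics (standard deviation of the
    medial-lateral and anterior-posterior CoP components), and instrument
    agreement via the intraclass correlation coefficient for absolute
    agreement and the mean absolute error, compared across processing
    variants. Includes a physics-based simulator of mat recordings and
    subject cohorts for end-to-end validation without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
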