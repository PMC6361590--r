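Package: nucfit
Title: Classical Nucleation Analysis of Protein Aggregate Size Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting first-order phase-transition (classical
    nucleation) behaviour in protein-aggregate size distributions measured
    by single-molecule localization microscopy and live-cell intensity
    imaging. Provides density-based clustering of localization maps,
    construction of empirical free-energy curves from cluster-size
    histograms, fits to the nucleation form a*n^(2/3) - b*n with
    self-consistent range selection, derived thermodynamic quantities
    (critical size and radius, nucleation barrier, surface-tension bounds),
    a kinetic Monte Carlo implementation of the Szilard
    production/condensation/clearance steady state with a master-equation
    oracle, analysis of photobleaching-corrected live-cell intensity
    traces, and a synthetic-data generator emulating the statistical
    structure of the microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
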