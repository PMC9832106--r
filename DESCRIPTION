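Package: hepasens
Title: Global Sensitivity Analysis of Post-Hepatectomy Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Closed-loop lumped-parameter (0D) model of the human
    circulation with a two-lobe hepatic sub-circuit and a virtual
    partial-hepatectomy operator; variance-based global sensitivity
    analysis of the cycle-averaged clinical outputs (portal pressure,
    portocaval gradient, arterial pressure, cardiac output, hepatic
    flows) via Saltelli pick-freeze estimation of Sobol indices; a
    physiologically filtered polynomial-chaos surrogate with marginal
    bases built by the discrete Stieltjes procedure, yielding analytic
    Sobol indices and a validated virtual patient population; and a
    weighted calibration of heart elastances to patient targets with an
    original and a reduced (filter-informed) strategy.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    fitdistrplus
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
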