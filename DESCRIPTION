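Package: ctcsim
Title: Simulation of Circulating Tumor Cell Kinetics and Blood-Clearing Devices
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic one-compartment model of single circulating tumor
    cells (CTCs) and CTC clusters in blood, with circadian release from the
    primary tumor, delayed re-seeding from established metastases, an optional
    lymphatic bypass, and extracorporeal or implanted blood-clearing devices.
    The delayed linear ODE system is integrated with a fixed-step midpoint
    (improved Euler) scheme implemented in C++. The package ships a registry
    of published device scenarios and computes the two headline device-design
    metrics: percent reduction in metastatic burden relative to an untreated
    control, and the days-to-equal-burden delay for long-horizon simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
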