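Package: hostpheno
Title: Seasonal Host-Parasite Dynamics and the Evolution of Host Phenology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-discrete model of a free-living, sterilizing parasite
    infecting a univoltine host with seasonal juvenile emergence.
    Within-season transmission follows delay differential equations solved by
    the method of steps with a compiled Dormand-Prince integrator; seasons are
    coupled by discrete maps for density-dependent host reproduction and
    parasite carryover.  Includes evolutionary invasion analysis (adaptive
    dynamics) of the host emergence start time and emergence period length:
    invasion fitness, selection gradients, trait-substitution ESS search,
    pairwise invasibility grids and equilibrium-density landscapes, plus a
    closed-form disease-free oracle used for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
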