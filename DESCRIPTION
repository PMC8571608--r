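Package: prospectsim
Title: Individual-Based Simulation of Prospecting and Informed Dispersal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic individual-based model of informed dispersal in a
    temporally autocorrelated patch network. Individuals use personal
    information (own breeding outcome) and public information (local
    conspecific breeding success) in emigration decisions, prospect a set of
    candidate patches, and settle according to inaccurate, accurate or
    deterministic patch-selection processes. Haploid dispersal loci
    (emigration probabilities, reaction-norm intercepts and slopes, number
    of prospected patches) evolve by maternal inheritance and mutation in a
    stage-structured, density-dependent metapopulation. Includes scenario
    grids for fixed-emigration and jointly evolving experiments, yearly
    summaries, and reporting of evolved trait means, prospecting spectra,
    reaction norms and density-quality relationships.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
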