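Package: grcopt
Title: Conductance-Based Cerebellar Granule Cell Models and Evolutionary
    Conductance Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds mono- and multi-compartment conductance-based models of
    the cerebellar granule cell (Hodgkin-Huxley gates, a 13-state Markov
    resurgent sodium scheme, and a calcium shell with a dynamic Nernst
    reversal), integrates them under current-clamp, voltage-clamp and ZAP
    chirp protocols, extracts electrophysiological spike features, and fits
    maximum conductances to feature templates with an indicator-based
    evolutionary algorithm (IBEA, additive epsilon indicator). Includes
    validation analyses for emergent properties (frequency-current slope,
    inward rectification, theta-band resonance, near-threshold oscillations,
    axonal conduction and dendritic back-propagation) and synthetic
    ground-truth parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tools,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
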