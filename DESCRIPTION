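Package: stellate
Title: Conductance-Based Models of Cerebellar Stellate Cells and
    Molecular-Layer Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compartmental conductance-based modelling of cerebellar
    molecular-layer stellate cells and the parallel-fiber to stellate-cell
    to Purkinje-cell microcircuit. Provides SWC morphology input/output and
    a statistical stellate-cell morphology generator, a library of 14
    Hodgkin-Huxley style ionic channel mechanisms with calcium dynamics, an
    implicit fixed-step cable-equation integrator (compiled core),
    Tsodyks-Markram short-term plasticity synapses (AMPA, NMDA, GABA-A),
    declarative stimulation protocols, electrophysiological feature
    extraction, a multi-objective evolutionary conductance optimizer, and
    microcircuit experiments quantifying the delay, low-pass and band-pass
    filtering that stellate-cell feed-forward inhibition imposes on
    Purkinje-cell responses.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    minpack.lm,
    signal
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
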