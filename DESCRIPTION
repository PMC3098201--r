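Package: prcsync
Title: Phase Response Curves and Synchronization of Excitatory Neuronal Networks
Version: 0.1.0
Authors@R:
    person("prcsync", "maintainers", email = "maintainers@prcsync.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying how firing
    frequency modulates phase response curves (PRCs) and network
    synchronization in excitatory networks of Type I versus Type II model
    neurons. Implements Morris-Lecar and Hodgkin-Huxley-type cortical
    pyramidal neuron models with a cholinergically modulated slow potassium
    (M-type) current, fixed-step Runge-Kutta network integration over
    directed Watts-Strogatz small-world graphs, the brief-pulse PRC
    protocol with frequency-current curves and delay-depth calibration,
    and spike-train synchrony statistics (pairwise mean phase coherence
    and the pooled-interval bursting measure).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
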