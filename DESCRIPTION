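Package: ca3net
Title: Anatomically Constrained Entorhinal-Dentate-CA3 Network Simulation
    and Space-Time Correlation Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Configurable-scale simulator and analysis toolkit for the rat
    entorhinal-dentate-CA3 circuit. Generates stochastic, topographically
    organized connectomes on an unfolded two-dimensional sheet (perforant
    path Gaussian terminal fields, mossy-fiber trajectories with
    region-dependent Poisson synapse placement, associational skew-Gaussian
    fields), simulates conductance-based reduced-compartment neurons with
    EPSP-calibrated AMPA/NMDA synapses, provides renewal-process spike
    sources, and characterizes population activity with three-dimensional
    space-time correlation maps (global and local) built from
    overlap-normalized pairwise spike-train cross-correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
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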