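Package: ca1theta
Title: Building-Block Features, Theta Rhythms and Phase Response Curves in
    CA1 Microcircuit Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for hippocampal CA1 microcircuit
    models built from two-regime Izhikevich neurons. Quantifies the
    "building block" features of pyramidal-cell excitability -- rheobase,
    post-inhibitory rebound and spike-frequency adaptation -- from
    current-step protocols; builds heterogeneous model databases by regular
    parameter sweeps and selects subpopulations by feature bands; simulates
    sparse excitatory-inhibitory spiking networks with conductance-based
    synapses and noisy drive that generate theta-frequency population
    bursts; quantifies rhythm frequency and power from population activity;
    and computes phase response curves under brief inhibitory current-pulse
    perturbations, with population-mean PRC features.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
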