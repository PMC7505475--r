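Package: lifnet
Title: Synapse Loss and Firing-Rate Homeostasis in Recurrent Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and mean-field analysis of inhibition-dominated
    excitatory-inhibitory networks of leaky integrate-and-fire neurons
    undergoing excitatory-synapse loss. Provides fixed-in-degree network
    construction with Poissonian external drive, a fast clock-driven
    integrate-and-fire simulator with exponential postsynaptic currents,
    spike-train statistics (rate, CV, Fano factor, E/I balance, synaptic
    contact area), twin-simulation perturbation-sensitivity analysis,
    firing-rate homeostasis by global synaptic scaling (unlimited and
    bounded) and by local calcium-driven structural plasticity, and a
    diffusion-approximation mean-field pipeline predicting stationary rates,
    effective connectivity and the spectral radius of the linearized
    dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    stats,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
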