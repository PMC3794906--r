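Package: homeoplast
Title: Homeostatic Structural Plasticity Simulation of Cortical Rewiring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-dimensional recurrent spiking cortical network in
    which every neuron grows and deletes discrete synaptic elements (axonal
    boutons, excitatory dendritic spines, inhibitory postsynaptic densities)
    according to Gaussian, calcium-dependent homeostatic growth curves. Vacant
    complementary elements merge into synapses with a distance-dependent
    Gaussian kernel, so network connectivity self-organizes from activity
    alone. The package provides the full focal-deafferentation protocol
    (lesion projection zone with center/border/peri regions, aberrant growth
    regimes, large lesions, peri-LPZ input manipulations, a high-density
    control), element turnover/survival/addition metrics, an axonal-overshoot
    analysis, a frozen-connectivity retinotopic remapping assay, population
    synchrony measures, and an outcome classifier for the repair/remapping
    scenario matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
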