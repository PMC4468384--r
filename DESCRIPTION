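Package: obpcsim
Title: Olfactory Bulb and Piriform Cortex Network Simulation with
    Noradrenergic Modulation
Version: 0.1.0
Authors@R:
    person("OBPC", "Maintainers", email = "maintainers@obpcsim.org",
           role = c("aut", "cre"))
Description: Simulates a reduced integrate-and-fire network model of the
    olfactory bulb (sensory neurons, periglomerular, mitral and granule
    cells) and piriform cortex (pyramidal, feedforward and feedback
    interneurons), with location-specific norepinephrine modulation of
    cell and synapse parameters via alpha1/alpha2-type dose-response
    curves, NMDA-coincidence Hebbian learning on cortical association
    fibers, and the detection-index and lifetime-sparseness statistics
    used to quantify odor detection, learning and recall.  Ships
    experiment drivers for detection grids over norepinephrine and odor
    concentration, locus-knockout comparisons, learn/recall protocols and
    perturbed-recall robustness curves, all deterministically seeded.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
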