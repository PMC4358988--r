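Package: tuftburst
Title: Coincidence Detection and Composite-Sigmoid Analysis of a Reduced
    Layer 5 Pyramidal Neuron Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reduced two-compartment (soma plus apical dendrite)
    conductance-based model of a layer 5 pyramidal neuron that exhibits
    backpropagation-activated calcium spiking and basal/tuft coincidence
    detection, together with the analysis stack built on top of it:
    spike-train and dendritic-plateau feature extraction, the critical
    frequency protocol (afterdepolarization size versus pulse frequency,
    sigmoid inflection), input-output frequency surfaces over basal and
    tuft synapse counts, fitting and comparison of composite,
    multiplicative and additive phenomenological sigmoid models, and von
    Mises orientation-tuning mechanism analysis with circular variance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
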