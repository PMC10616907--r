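Package: microte
Title: Effective Microconnectomes from Spike Trains via Transfer Entropy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers directed effective networks and excitatory/inhibitory
    neuron identities from millisecond-binned spike rasters using
    delay-resolved transfer entropy and sorted local transfer entropy,
    thresholded against jitter-surrogate null models. Includes a
    Bernoulli-GLM spiking-network simulator with ground-truth synaptic
    connectivity for validation, cortical-layer assignment from
    depth-density profiles, network characterization (degree, k-core,
    weighted minimum feedback vertex sets, interlayer weight matrices),
    and permutation-based group statistics across cortical region groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
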