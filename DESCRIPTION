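Package: alclassify
Title: Spiking Neural Network Classifier Modelled on the Insect Antennal Lobe
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A portable, single-machine implementation of a bio-inspired
    spiking-network classifier for multivariate data. Real-valued inputs are
    encoded by virtual receptors placed with the neural gas vector-quantization
    algorithm, converted to population rate codes, and fed through a
    three-layer network of leaky integrate-and-fire neurons with lateral
    inhibition and a winner-take-all readout. Two supervised plasticity
    schemes are provided: symmetric spike-timing-dependent plasticity driven
    by a teaching signal, and a per-sample perceptron rule applied between
    presentations. Includes an MNIST IDX reader, a synthetic Gaussian-cluster
    data generator, stratified cross-validation helpers, and a benchmarking
    pipeline that sweeps receptor counts and class sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
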