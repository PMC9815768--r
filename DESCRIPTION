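Package: kernelregimes
Title: Center-Selection Regimes for Budgeted Radial Basis Function Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation framework for studying how a radial basis function
    classifier should spend a limited budget of Gaussian kernel centers, a
    question motivated by expansion recoding in the cerebellar granule cell
    layer.  Provides an entangled Gaussian-mixture task generator with label
    noise and task-irrelevant input dimensions, Gaussian-kernel and
    random-projection expansion layers, six competing center-selection
    regimes (random, regular, frequency, k-means, support-vector and online
    novelty-criterion selection), a closed-form ridge-stabilised linear
    readout, and an experiment grid runner that aggregates accuracies over
    seeds and ranks the regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
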