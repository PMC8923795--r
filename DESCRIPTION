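Package: fsgp
Title: Genetic-Programming Classification with Embedded Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-life-cycle genetic-programming (GP) binary classifier for
    EEG-derived band-power feature tables. Evolves expression-tree classifiers
    with ramped half-and-half initialization, structural-diversity enforcement,
    elitism, and hill-climbing crossover and mutation; during the first half of
    the evolutionary run it accumulates per-feature occurrence weights over
    above-average classifiers, then partitions features into a kept (Fso) and a
    purged (Fno) subset and rewrites every tree in the population so that no
    purged feature survives, yielding feature selection and classification in a
    single GP run. Includes a Gaussian class-conditional synthetic-data
    generator with a closed-form Bayes-accuracy oracle, hold-out evaluation
    utilities, confusion-matrix metrics, an exact and normal-approximation
    Mann-Whitney U test for comparing run-accuracy samples, and a command-line
    experiment harness.
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
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
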