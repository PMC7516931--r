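Package: tensorMRF
Title: Tensor Markov Fields: Gibbs Measures, Hammersley-Clifford
    Machinery and Information-Theoretic Structure Inference on
    Multilayer Graphs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Exact machinery for Markov random fields whose variables are
    tensor-indexed (variable i observed in layer h), i.e. multilayer
    graphical models for multi-omic style data. Provides multilayer
    graphs with cliques, separation and Markov blankets; exact Gibbs
    fields on small configuration spaces (energy, partition function,
    local characteristics, exact sampling); the Moebius-inversion
    construction of clique potentials from a strictly positive joint
    distribution together with machine verification of the two
    Hammersley-Clifford conditions; conditional-independence testing on
    exact joint tables and on empirical samples; minimal I-map
    recovery; mutual-information adjacency and strength hypermatrices
    with multidegree tensor centralities; and a seeded synthetic-data
    generator of planted multilayer dependency structures so that every
    theoretical property is a runnable test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
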