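Package: idionet
Title: Bitstring Model of the Idiotypic B-Cell Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Minimal bitstring model of the idiotypic network of
    B-lymphocyte clones. Builds the base graph linking nodes of nearly
    complementary bitstring idiotypes, runs the stochastic influx /
    window-rule cellular automaton (optionally with permanently occupied
    self nodes), derives the closed-form group sizes and link matrix of
    emergent modular architectures, identifies patterns in real time from
    the center-of-mass vector, and solves the modular mean-field theory
    including its modifications in the presence of self.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Matrix,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'bitspace.R'
    'architecture.R'
    'automaton.R'
    'observables.R'
    'meanfield.R'
    'io.R'
    'protocols.R'
    'idionet-package.R'
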