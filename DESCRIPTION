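Package: navdup
Title: Neofunctionalization Analysis of Duplicated Sodium-Channel Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether a young gene duplicate has acquired a
    new function, built around the comparative and biophysical analyses used
    for duplicated muscle sodium-channel (scn4a-family) genes in weakly
    electric fish. Implements minimum-mutation parsimony mapping of amino-acid
    substitutions onto the three branches of a paralog/paralog/outgroup trio,
    weighted kernel substitution-density profiles with a relative-density
    hotspot statistic and a Monte-Carlo permutation threshold, Goldman-Yang
    codon-model (F3X4) likelihoods with one-ratio and branch (two-ratio)
    dN/dS fits compared by likelihood-ratio test, quantification of
    persistent sodium current, activation/steady-state-inactivation Boltzmann
    fits and recovery from inactivation from voltage-clamp trace sets, and
    expression-table and qPCR (2^-ddCq) utilities. Every analysis has a
    matched synthetic-data generator so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    ape,
    signal,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
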