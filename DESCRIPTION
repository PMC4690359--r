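Package: stratphylo
Title: Parsimony Phylogenetics, Stratigraphic Congruence, and Ancestral
    Areas for Fossil Morphological Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for discrete morphological character
    matrices of fossil taxa: maximum-parsimony tree search (random stepwise
    addition with tree bisection-reconnection branch swapping, minimum-length
    branch collapsing, constrained searches, Bremer and bootstrap supports),
    ensemble homoplasy indices, stratigraphic congruence metrics (minimum
    implied gap, gap excess ratio, modified Manhattan stratigraphic measure)
    under topological and first-appearance-age uncertainty, ghost-lineage
    time calibration, and ancestral-area reconstruction on fixed topologies
    under parsimony and a single-rate Mk likelihood model with unit or
    ghost-lineage branch lengths. Includes parsers for TNT and NEXUS
    matrices and a simulator that generates matrices, trees, ages, and
    geographic characters with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
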