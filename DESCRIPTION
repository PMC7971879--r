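Package: blastosem
Title: Multiscale Subcellular-Element Simulation of Mouse Blastocyst Patterning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-dimensional multiscale simulator of preimplantation mouse
    embryo development from the zygote to the 128-cell blastocyst. Couples
    per-cell stochastic Nanog/Gata6/Fgf4/Fgfr2/Erk gene-regulatory dynamics
    with subcellular-element cell mechanics under selective, cell-type
    dependent adhesion, zona pellucida confinement and blastocoel cavity
    growth. Includes ligand-receptor adhesion scoring from single-cell
    expression with Gaussian-mixture binarization, phenomenological adhesion
    hypotheses, a bipartite-matching pattern loss score with outcome
    classification, synthetic single-cell expression generators, and scenario
    runners for Fgf-signaling-timing and adhesion-hypothesis experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    mclust,
    Matrix
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
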