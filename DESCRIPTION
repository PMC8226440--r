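Package: pedmate
Title: Pedigree-Based Mate Selection and Effective Population Size
    Management for Small Captive Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the genetic management of small captive (ex situ)
    populations from studbook pedigrees: tabular kinship/coancestry and
    inbreeding computation, pedigree completeness (equivalent complete
    generations), generation interval, effective population size
    estimators based on individual increases in inbreeding (NeF) and
    pairwise increases in coancestry (NeC), a catalogue of 23
    mate-selection strategies defined as constrained minimisation of
    parent- and offspring-coancestry objectives, an exact and
    simulated-annealing mating-plan optimizer, and a multi-replicate
    discrete-generation simulator that compares strategies by the
    evolution of effective population size.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
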