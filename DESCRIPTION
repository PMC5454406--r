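Package: tipirt
Title: SHAPE-Directed Pseudoknot Structure and Dimerization Analysis of
    Retrotransposon RNA Leaders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for structure-function studies of
    retroelement RNA 5' leaders, built around the Ty1 TIPIRT domain.
    Processes chemical-probing (SHAPE) intensities into normalized
    composite reactivity profiles with replicate quality control,
    predicts minimum-free-energy secondary structures under a
    nearest-neighbor model with reactivity-derived pseudo-free-energy
    restraints, discovers H-type pseudoknots with a forced-helix
    heuristic, decomposes structures into stems and loops, extracts the
    pseudoknot core (S1/L2/S2), scans apical hairpin motifs for
    kissing-loop complementarity and palindromes, classifies alignment
    columns into three conservation categories on reference
    coordinates, and summarizes retrotransposition-frequency assays
    with distribution-free median confidence intervals. A synthetic
    data generator with known ground truth supports end-to-end testing
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
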