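Package: kekule
Title: Fast Approximate Kekulization of Large Polycyclic Structures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assigns explicit single, double, triple and cumulated bond
    orders to conjugated polycyclic molecular graphs (kekulization) using
    a randomized bond-alternation heuristic with shuffle restarts and an
    exact backtracking fallback.  Handles pi-deficiency-2 (acetylenic and
    cumulenic) carbons, which makes graphynes and graphdiynes tractable.
    Includes parametric generators for benchmark structure families
    (armchair carbon nanotubes, graphene ribbons, graphynes GY1/GY7,
    graphyne nanotubes, fullerenes C20/C60 and their aza-analogs,
    porphine, and linear/cyclic/Moebius polycyclopentadienes), MDL
    molfile (V2000/V3000) and XYZ input/output, and repeated-trial
    statistics over randomized runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ChemmineR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
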