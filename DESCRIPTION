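Package: ssassign
Title: Automated Chemical Shift Assignment for Solid-State NMR Peak Lists
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Probabilistic backbone and side-chain chemical shift assignment
    for magic-angle-spinning solid-state NMR data. Reads peak lists (Sparky,
    XEASY, tab-separated) and protein sequences, assembles per-residue spin
    system matrices from carbon/nitrogen-detected 2D and 3D experiments using
    CO(i-1)/N(i)/CA(i) root triples, links spin systems into di-peptide
    chains, scores pentapeptide fragments against the sequence, and computes
    per-residue assignment probabilities by loopy belief propagation on a
    factor graph with soft one-to-one exclusion. Includes a synthetic
    peak-list simulator driven by deposited chemical-shift tables, writers
    for NMR-STAR 2.1/3.1 and Sparky resonance lists, referencing-offset
    detection, and completeness/correctness evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
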