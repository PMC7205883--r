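Package: linearends
Title: Terminal-Region Turnover Analysis for Linear Bacterial Replicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for the terminal regions of linear bacterial
    replicons (Streptomyces-type invertrons). Delimits terminal inverted
    repeats (TIRs) from the read-depth doubling signal on collapsed
    assemblies, recovers telomeres by greedy consensus read walking, types
    telomere stem-loop architecture by base-pair-maximising palindrome
    selection, builds neighbor-joining K2P telomere phylogenies with
    bootstrap support and tests their congruence against a genome tree,
    scans colinear terminal regions for homologous recombination with a
    consensus of permutation-based detectors, and inventories terminal
    protein (Tap/Tpg, GtpB/GtpA) homologues at identity/coverage cutoffs.
    Ships a population simulator for conspecific linear chromosomes with
    known TIRs, telomeres and rearrangement history so every stage is
    testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
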