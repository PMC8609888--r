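Package: tollscan
Title: Survey, Classification and Evolutionary Analysis of Toll-Like Receptors
Version: 0.9.0
Authors@R:
    person("tollscan", "developers", email = "tollscan@example.org",
           role = c("aut", "cre"))
Description: Detects Toll-like receptors (TLRs) in protein sequence sets by
    domain architecture (leucine-rich repeats, cysteine-rich caps, a
    transmembrane segment and a TIR domain), classifies them into V-type/scc
    and P-type/mcc structural types, collapses per-species redundancy at a
    similarity threshold, post-processes alignments (core-region extraction,
    gappyout trimming, region masking, indel carrier detection), assigns gene
    tree tips to the alpha/beta/gamma TLR clades using bootstrap-supported
    anchored clades, reconstructs clade gains and losses on a fixed metazoan
    species tree under Dollo parsimony, ranks alternative duplication
    scenarios, and calls developmental expression from stage-specific
    abundance tables (TPM followed by cross-stage TMM normalization and a
    fixed detection threshold). A seeded synthetic-data module generates
    every input with known ground truth so the full pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
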