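Package: padifr
Title: Per-Atom Score Contribution Interaction Fingerprints for Docking
    Pose Rescoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-atom score-contribution interaction fingerprints
    (PADIFs) from tabular per-atom scoring-function exports of protein-ligand
    complexes, merges several reference complexes into a single median
    fingerprint with a frequency-based weighting matrix, and rescores docking
    poses against that consensus with an overlap-penalized similarity score.
    Includes virtual-screening evaluation (ROC AUC, enrichment factors), a
    combined conventional-plus-fingerprint ranking, a synthetic-data generator
    that emulates reference and active/decoy pose sets, and a command-line
    interface covering the full simulate/build/score/evaluate workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
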