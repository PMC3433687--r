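Package: hotspotter
Title: Detection and Prediction of Protein Phosphorylation Hotspots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing and predicting phosphorylation hotspots
    in protein sequences. Detects hotspots as runs of at least four
    experimentally determined phosphorylation sites spaced at most ten
    residues apart, analyses nearest-neighbor inter-site spacing within
    peptide-covered regions against phospho-flag and sequence-shuffle
    randomization nulls, encodes sequence windows as 420-dimensional
    normalized monomer plus directed-dimer composition vectors, trains a
    radial-basis-function support vector machine with asymmetric class costs
    and hotspot-grouped cross-validation, scans whole proteomes with
    positive-run consolidation and S/T/Y content filtering, quantifies
    overlap with intrinsically disordered regions against a random-placement
    null, and simulates seeded synthetic phosphoproteome benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
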