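Package: peptidegate
Title: Clade-Contrast Screening and Functional Analysis of Peptide-Gated
    Sodium Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying candidate determinants of neuropeptide
    sensitivity in trimeric DEG/ENaC sodium channels. Implements the
    comparative pipeline from a clade-labeled multiple sequence alignment
    to a ranked list of clade-specific residues: length and redundancy
    curation of aligned sequences, column-wise foreground-conservation
    versus background-divergence scanning with a physicochemical class
    scheme, mapping of candidates onto trimeric structures to detect
    inter-subunit pocket residues, and electrophysiology statistics
    (per-recording Hill fits, paired potency ratios, Monte-Carlo Dunnett
    classification of mutants, and paired fold-enhancement). A synthetic
    data module generates ground-truth-annotated alignments, C3-symmetric
    toy trimers, dose-response tables and current traces for benchmarking
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    multcomp,
    mvtnorm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
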