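Package: strucphylo
Title: Structure-Based Phylogenetics from Predicted Protein Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers phylogenies from protein structure models rather than
    sequences. Provides pLDDT-driven quality control of AlphaFold-style
    models (terminal window trimming, fraction-based rejection and removal
    of low-confidence residues), sequence-order-independent pairwise
    superposition and progressive common-core structural alignment,
    conversion of structural similarity scores to evolutionary distances,
    neighbor-joining tree inference, Robinson-Foulds tree comparison, and a
    block-based jackknife procedure for branch support calibrated by a
    sampling-fraction sweep. Includes a synthetic-structure simulator with
    a known generating tree so every pipeline stage can be benchmarked
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
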