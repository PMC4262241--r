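Package: netdriver
Title: Network Enrichment Analysis for Driver Mutation Prioritization in
    Individual Cancer Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Distinguishes candidate driver from passenger somatic mutations
    in individual tumor genomes by network enrichment analysis (NEA) on a
    global functional-coupling network. Connectivity between a mutated gene
    and a gene set is scored as a z-score calibrated against degree-preserving
    (Maslov-Sneppen) network randomizations. Three parallel tests -- a single
    point mutation against the rest of the sample's mutated gene set, a
    copy-number-altered gene against the mutated gene sets of its carrier
    genomes, and any gene against a collection of cancer pathways -- are
    combined with Fisher's chi-square method together with a Fisher-exact
    co-occurrence screen, then ranked under Benjamini-Hochberg control.
    Includes ROC-based benchmarking of candidate global networks by
    leave-one-out recovery of pathway membership against degree-matched
    negatives, and a synthetic-cohort generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    igraph,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
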