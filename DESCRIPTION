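Package: mespath
Title: Running-Sum Pathway Enrichment and Mitochondrial Plate-Assay Derivations
Version: 0.1.0
Authors@R:
    person("mespath", "developers", email = "mespath@example.org",
           role = c("aut", "cre"))
Description: Tools for longitudinal bulk-transcriptome and mitochondrial
    function studies. Implements a running-sum gene-set enrichment statistic
    (the Maximum Estimate Score, MES) over log2-fold-change-ranked gene lists
    with exhaustive or sampled permutation null distributions,
    Benjamini-Hochberg false discovery rate control, and signed Z-score
    conversion for heatmap matrices; Gene Ontology keyword gene-set
    construction and one-sided Fisher exact overrepresentation with Bonferroni
    correction; derivation procedures for plate-based mitochondrial assays
    (Seahorse-style respiratory states and electron-flow complex activities,
    calcium retention capacity from pulsed fluorescence traces, hydrogen
    peroxide production slopes, ATP standard-curve quantification); exact
    small-sample Mann-Whitney tests and effect-size summaries; and a seeded
    synthetic-data generator that emulates every pipeline input with known
    ground truth so the full workflow runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
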