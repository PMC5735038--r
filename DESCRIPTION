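Package: repscore
Title: Allelic Repression-Score Analysis of Chromosome-Wide Silencing
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies cis-acting, allele-specific transcriptional silencing
    from allele-split nascent-RNA read counts in hybrid cell lines. Implements
    CPM normalization and allelic splitting of gene counts, the per-gene
    Repression Score (RS) with calibration against a random-RS background
    (cRS), permutation-based per-gene p-values combined across replicates by
    Fisher's method with Benjamini-Hochberg correction, sliding-window scans
    that locate the maximum-silencing region of a chromosome, inference of the
    transgene-bearing chromosome and silenced allele, and an allelic ATAC-seq
    accessibility differential (ddscore) with chromatin-state aggregation and
    rank-sum comparison. Ships a synthetic-data generator that emulates
    allele-split count tables with a known silenced chromosome so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
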