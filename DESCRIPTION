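Package: barcodeChIP
Title: Chromatin Binding Scores from Barcoded Clone Pools by ChIP-Barcode Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screens that read out protein-DNA binding at a barcoded
    locus across thousands of tagged yeast clones pooled in one culture.
    Implements amplicon barcode extraction (constant-region anchoring, sample
    index and clone barcode read-off, count tabulation), decoding of arrayed
    384-well libraries from row- and column-pool sequencing, the count
    preprocessing chain (plate median normalization, low-input filtering,
    log2 IP/input scores, quantile normalization), empirical-Bayes moderated
    one- and two-sample tests with Benjamini-Hochberg FDR for binder and
    condition-contrast calling, Fisher and running-sum gene-set enrichment,
    and a ground-truthed simulator of the whole experimental design for
    offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    optparse
biocViews: Software, Sequencing, ChIPSeq, Preprocessing, DifferentialExpression, GeneSetEnrichment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
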