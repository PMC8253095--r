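Package: cistromics
Title: Multi-Sample Cistrome Concordance Analysis for ChIP-Seq and RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify concordance of transcription-factor cistromes
    across related tumour samples. Builds dual-caller consensus peak sets with
    quantile-fence quality control, decomposes merged consensus regions into
    sample-shared and sample-specific classes, constructs length-matched random
    ("noise") region nulls, computes CPM-normalised fragment counts and binned
    signal matrices centred on regions, stratifies candidate sites by histone-mark
    signal with seeded k-means, links sites to genes by TSS proximity, tests gene
    sets by the hypergeometric distribution, scores PWM motif enrichment against a
    matched shuffled background, runs a simplified negative-binomial Wald test for
    two-group differential expression, and clusters samples by Pearson correlation
    with complete linkage. Ships a deterministic synthetic-data generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
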