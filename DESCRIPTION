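Package: p53eff
Title: Inferring p53 Transcriptional Effectiveness from Bulk Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to infer per-sample p53 transcriptional effectiveness from
    log2 gene expression matrices. Per-target response functions are calibrated
    on nontumor samples, each tumor sample is scored by the slope of its
    measured-vs-expected expression over a panel of p53 target genes, and
    samples are classified as normal-like or p53-impaired. Includes a
    from-scratch robust biweight midcorrelation (bicor) with Student-t
    significance, anchor-vs-panel correlation tables, correlation restoration
    analysis after removal of impaired samples, a synthetic-data generator with
    known impairment ground truth, and an end-to-end reproducible pipeline with
    readers for tab-delimited and GEO series-matrix expression formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
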