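Package: mtecdiv
Title: Self-Antigen Representation Diversity in Thymic Epithelial Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how broadly a reference cell population (such as
    mature medullary thymic epithelial cells, mTECs) mirrors the
    transcriptomes of peripheral tissues.  Provides expressed-gene counting
    under a reads-per-nucleotide threshold, tissue-restricted antigen (TRA)
    detection from FPKM panels, leave-one-out tissue-specificity overlap
    matrices, splice-junction based alternative-splicing metrics including
    tissue-restricted junction detection, and A-to-I / C-to-U RNA-editing
    statistics (per-site editing levels, editing rates, hyper-edited read
    classification and site density, per-site Fisher comparisons with
    Benjamini-Hochberg correction).  Includes a multi-tissue synthetic data
    generator with planted ground truth for validating every analysis step.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    DESeq2,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
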