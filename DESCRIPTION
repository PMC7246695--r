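Package: pianoseq
Title: Classification of Early Transcriptional Responses to OSKM
    Reprogramming into Proper, Insufficient, Aberrant and No-Response
    Categories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A bulk RNA-seq pipeline for scoring the reprogramming
    legitimacy of every gene's early transcriptional response to the
    Yamanaka factors (OCT4, SOX2, KLF4, c-MYC). Starting from a raw
    gene-by-sample count matrix of fibroblasts, embryonic stem cells and
    OSKM- or GFP-transduced fibroblasts at 48 and 72 hours, the package
    computes median-of-ratios size factors, runs a negative-binomial Wald
    test for the study's five contrasts, builds the up- and
    down-reprogramome from fibroblast versus ESC expression, and assigns
    each gene one of the PIANO categories (proper, insufficient, six
    aberrant types, refractory/no response). It also provides generic
    Fisher's-exact overrepresentation testing against GMT gene sets and a
    negative-binomial synthetic-data generator with planted category
    structure for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
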