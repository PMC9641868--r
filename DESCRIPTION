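Package: psgtools
Title: Dating, Developmental Dynamics and Classification of Pseudogenes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A coordinate- and count-based toolkit for pseudogene biology:
    synteny/parsimony dating of pseudogene origins on a species ladder with
    branch-midpoint ages, tau tissue and developmental-stage specificity,
    detection of developmentally dynamic pseudogenes by cubic regression on
    log time, chromosomal traffic enrichment with Fisher's exact test,
    promoter and regulatory-feature overlap metrics, cancer-type-specificity
    labeling, and a fully seeded synthetic-data generator with recorded
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
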