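Package: markerNBC
Title: Naive Bayesian k-mer Classification and Evaluation of DNA Barcoding Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the taxonomic resolution of DNA barcoding
    markers (e.g. plant chloroplast loci such as matK, rbcL and trnL) with a
    Wang-style naive Bayesian k-mer classifier. Provides Greengenes-style
    six-rank taxonomy input/output, reference-set curation and per-species
    balancing, classifier training with bootstrap confidence estimation,
    exhaustive leave-one-out cross-validation, per-rank accuracy and
    per-taxon precision/recall/F1 summaries with problematic-genus
    diagnostics, and a hierarchical sequence simulator for end-to-end
    validation without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    caret,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
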