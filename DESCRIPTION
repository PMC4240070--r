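Package: mirgba
Title: miRNA Target Integration, Enrichment, and Guilt-by-Association
    Disease Networks for CNV Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterise the microRNA content of a copy-number
    variant region and trace its downstream gene network. Implements
    genome-wide windowed miRNA-density percentile statistics, integration
    of two target-prediction tools by percentile transformation with
    arm and tool averaging, gene-set enrichment of miRNA target lists by
    one-tailed Fisher's exact test with Benjamini-Hochberg correction and
    a multi-threshold consensus filter, additive guilt-by-association
    scoring of a weighted protein-interaction network seeded with disease
    candidate genes, and overlap testing of miRNA-mechanism target sets
    against the resulting network. Includes a seeded synthetic-data
    generator that emulates every input format with planted statistical
    structure, so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
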