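Package: yreflank
Title: Flanking-Sequence Analysis of bZIP Transcription Factor Response Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the DNA sequences flanking basic leucine
    zipper (bZIP) response elements shape protein-DNA recognition, built
    around the yeast AP-1 factor Yap1 and its response elements (YREs).
    Provides geometric detection and unit-weight strength scoring of
    hydrogen bonds, salt bridges and apolar contacts in protein-DNA
    structural ensembles; base-pair-step helical parameter (shift, slide,
    rise, tilt, roll, twist) extraction, rebuilding, distribution and
    bound-versus-unbound alteration analysis over response elements and
    their flanks; motif scanning, single-instance filtering,
    flank-composition grouping and expression-dispersion statistics for
    random promoter libraries; and seeded synthetic generators that plant
    recoverable ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
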