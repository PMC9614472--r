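Package: shadeclass
Title: Classification of PIF Direct Target Genes and Transcript Versus
    H3K4me3 Timing in Shade-Avoidance Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying PHYTOCHROME-INTERACTING FACTOR (PIF)
    direct target genes of Arabidopsis thaliana into etiolation (E),
    etiolation-plus-shade (ES) and shade (S) response classes from
    multi-contrast differential-expression evidence, and for comparing the
    timing of shade-induced transcript changes with H3K4me3 changes at
    transcription start sites. Includes strict and relaxed significance
    calls on log2 fold changes, rule-based group assignment with anomaly
    exclusion and relaxed-cutoff resorting, 300-bp TSS-window read
    counting, median-of-ratios normalization with a variance-stabilizing
    log transform, 0-100 min-max profile scaling, onset and transient-dip
    detection with RNA-to-mark lag estimation, and a seeded negative
    binomial simulator of RNA-seq and H3K4me3 window-count time courses
    with planted class structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
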