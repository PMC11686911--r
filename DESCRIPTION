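Package: ciscope
Title: Allele-Resolved Chromatin Contact and Regulatory Variant Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Allele-specific epigenomic analysis around a promoter epimutation:
    demultiplexing of aligned reads by a heterozygous reporter variant (SNV or
    small deletion), UMI-deduplicated 4C viewpoint contact profiles over
    restriction fragments with count-balanced smoothing windows, per-window
    two-sided Fisher exact differential contact calling with BH-FDR control,
    permutation tests for overlap between differential contacts and accessible
    regions, consensus peak voting, phase-aware sliding-window rare-variant
    burden, and position-weight-matrix scanning with exact score p-values to
    classify variants that disrupt activator, repressor or insulator binding
    sites. Includes seeded generators that simulate every input format so the
    whole pipeline is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
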