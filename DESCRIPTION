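Package: msisweep
Title: Microsatellite Instability Calling and Cohort Analysis from Tumour/Normal Repeat-Length Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds reference catalogues of microsatellite repeats (mono- to
    tetranucleotide tracts of 6-60 bp) from genomic sequence, calls somatic
    microsatellite instability (MSI) events in tumour/normal pairs by
    comparing per-locus read-length distributions with a two-sample
    Kolmogorov-Smirnov test under Benjamini-Hochberg FDR control, classifies
    coding events as frameshift or in-frame, aggregates calls into cohort
    recurrence and enrichment statistics (tumour-type specificity, MSI-H
    specificity, UTR/coding bias, chromatin-state enrichment), and predicts
    MSI status with a random forest wrapped in Mondrian conformal prediction.
    Ships a PCR-stutter slippage simulator that generates references, allele
    length tallies, aligned reads and labelled cohorts with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    randomForest,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    caret,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
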