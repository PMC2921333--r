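Package: thyromir
Title: Differential Expression and Target Integration for
    Thyroid-Hormone-Responsive miRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a liver transcriptomics workflow
    for detecting thyroid-hormone-responsive miRNAs and mRNAs: two-channel
    microarray differential expression with negative-control probe flagging,
    global lowess (MA) normalization, shrinkage-variance F statistics and
    residual-shuffling permutation p-values; TaqMan low-density-array miRNA
    differential expression with a within-condition residual bootstrap null
    for the one-way ANOVA F; delta-delta-Ct relative quantification with
    standard-curve efficiency checks; and integration of miRNA fold changes
    with target predictions from two sources via union, filtering and
    direction-concordance reporting. Ships a synthetic-data generator with
    known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
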