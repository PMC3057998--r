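Package: lineone
Title: Intragenic LINE-1 Elements and Host Gene Repression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether genes hosting intragenic LINE-1 (L1)
    retrotransposons are preferentially repressed in cancer and in
    experimentally demethylated cells. Provides interval-based classification
    of L1 elements as intragenic or intergenic, structural feature screens
    (chi-square and pooled-variance t-tests), probe-level two-group expression
    calling with unique/homologous probe aggregation rules, 2x2 enrichment
    statistics (Pearson chi-square, odds ratio, Woolf confidence interval),
    cross-experiment regulation concordance (CU-DREAM), AGO2 binding-site
    association and signed-distance proximity histograms around intragenic
    L1s, COBRA methylation percentages, and a synthetic-data generator with
    planted effects so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
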