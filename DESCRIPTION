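Package: tagrates
Title: Division and Death Rate Estimation from Neutral Sequence-Tag Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates microbial division and death rates from the drift in
    neutral sequence-tag (barcode) frequencies together with colony-forming-unit
    time series. Tag-frequency drift is aggregated into a founder population
    size, technical bottlenecks (pipetting, limited sequencing depth) are
    corrected analytically by subtracting their mean inverse sample sizes, and a
    bottleneck sensitivity measure flags fragile estimates. Includes a
    vectorized tau-leaping birth-death simulator with multinomial bottleneck
    sampling, a barcode FASTQ counting pipeline with a binomial
    sequencing-error model for removing spurious reads, a plasmid-segregation
    comparator, tag-extinction forecasting, and synthetic-data generators with
    exact ground-truth bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
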