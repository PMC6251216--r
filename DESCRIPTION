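Package: mendelscan
Title: Mapping Monogenic Recessive Traits from Biparental Crosses with Dual
    Variant Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for cloning a monogenic recessive-trait
    gene from an F2 cross: Mendelian segregation goodness-of-fit tests,
    per-variant genotype-phenotype association scans with peak-interval
    definition, dual variant screening against a diversity panel and a
    bulked-segregant (BSA) pool, candidate-gene assignment from gene models,
    and molecular-consequence reconstruction for splice-donor-destroying
    deletions (intron retention, frameshift, premature stop, domain
    disruption). Ships a seeded simulator for every input the pipeline
    consumes - recombining F2 populations under the Haldane map function,
    germplasm panels and pooled read counts - so the whole workflow is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
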