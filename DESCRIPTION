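Package: scentmhc
Title: Odour-Gene Covariance Between Feather Volatiles and MHC Genotype
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether volatile chemical profiles carry
    information about major histocompatibility complex (MHC) genotype, built
    around the dyadic design used in studies of odour-based mate choice in
    seabirds. Provides GC-MS peak-table standardization and principal
    components analysis of chemical profiles; functional MHC distances from
    five amino-acid physico-chemical descriptors (z-scales); individual MHC
    diversity and pairwise genotype distance matrices; interaction linear
    models with Type III tests and simple slopes; partial Mantel and
    rectangular partial Spearman permutation tests on distance matrices;
    exhaustive BIO-ENV compound-subset selection; and a seeded synthetic
    cohort generator that emulates the study design for power and
    calibration analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    car,
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
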