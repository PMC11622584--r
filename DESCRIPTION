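Package: semenmeth
Title: Cell-Type Deconvolution and Multifactor Modelling of Targeted
    Bisulfite Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing targeted bisulfite sequencing methylomes of
    heterogeneous tissues such as semen and buccal swabs. Assembles
    coverage-filtered methylation matrices from CGmap call files with
    k-nearest-neighbour imputation, estimates per-sample cell-type
    composition by non-negative least squares against reference methylomes,
    fits a multivariate multiple regression ("multifactor") model of
    methylation on phenotypic factors via the Moore-Penrose pseudoinverse
    with leave-one-out cross-validation, and selects factor-associated CpG
    sites through a three-filter procedure (observed-vs-predicted
    correlation, Benjamini-Hochberg adjusted significance, highest absolute
    coefficient) split by coefficient sign. Includes a fully seeded
    synthetic-cohort generator (reference methylomes, mixtures, age and
    batch effects, binomial read noise) so every stage is testable without
    external data.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
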