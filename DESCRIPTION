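Package: clonotrackr
Title: Longitudinal Single-Cell Immune-Repertoire Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal single-cell T-cell and B-cell receptor
    repertoire analysis. Joins transcriptome-derived cell annotations with
    VDJ clonotype contigs by cell barcode, classifies clonotypes as sporadic
    or sustained across sampling time points, subtracts baseline and
    cross-study repertoires around vaccination to isolate vaccine-associated
    clonotypes, detects dynamically expanding or contracting clonotypes,
    profiles repertoire diversity (Shannon entropy, V-gene usage, isotype
    composition), and compares PBMC cell-type compositions across groups and
    measurement modalities. A seeded cohort simulator with planted ground
    truth (persistent clone pools, power-law clone sizes, vaccination
    perturbations) makes every stage verifiable at desk scale.
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
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
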