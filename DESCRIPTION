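Package: vtburden
Title: Variable-Threshold Rare-Variant Burden Testing and De Novo
    Mutation Models for Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based rare-variant association analysis for case-control
    cohorts using a variable-threshold collapsing test with permutation
    calibration, rule-based variant and trio de novo filtering with audit
    trails, a trinucleotide-context background mutation model with exact
    Poisson burden testing, and single-cell expression-based candidate-gene
    ranking. Includes a synthetic-cohort generator with known ground truth
    so every stage can be exercised and calibrated without access-controlled
    genomic data. All user-facing functions take data frames and return
    tibbles so analyses compose with the pipe.
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
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
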