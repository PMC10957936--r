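Package: ccgraph
Title: Cohort Causal Graphs from Tiered, Mixed-Type Data with Missing Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Constraint-based causal structure learning for longitudinal
    cohort studies. Implements a tier-constrained PC-stable algorithm that
    learns a maximally oriented partially directed acyclic graph (MPDAG)
    from mixed discrete and continuous variables, with conditional-Gaussian
    likelihood-ratio and Fisher-z conditional independence tests, test-wise
    deletion and multiple-imputation pooling (Rubin's rules and the D2
    chi-square combination) for missing data, chained-equations imputation,
    bootstrap graph ensembles with edge- and path-stability summaries,
    MPDAG path queries (possible ancestors, directed and partially directed
    paths), graph comparison metrics (Hamming and structural Hamming
    distance, consensus graphs), and a synthetic tiered cohort generator
    with missing-at-random masking for end-to-end validation.
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
    igraph,
    jsonlite,
    nnet,
    purrr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
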