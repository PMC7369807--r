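Package: healstreet
Title: Healing-Environment Evaluation of Urban Street Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating how well dense urban street spaces function
    as healing environments. Implements hierarchical Analytic Hierarchy
    Process (AHP) weighting with geometric-mean and principal-eigenvector
    priority derivation and the consistency-ratio test, two-level fuzzy
    comprehensive evaluation (FCE) with the weighted-average synthesis
    operator and maximum-membership classification, behavioral-mapping
    aggregation for street observation logs, and axial-graph space-syntax
    measures (connectivity, integration, choice). Ships the complete Macao
    old-town worked example as plain-text fixtures and a seeded synthetic-data
    generator so every pipeline stage can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
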