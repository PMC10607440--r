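Package: hexrot
Title: Algorithmic Two-Dimensional Mental-Rotation Items and Their
    Psychometric Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating a public-domain
    two-dimensional mental-rotation measure. Enumerates polyominoes and
    jigsaw-style puzzle cuts, assembles hexomino-array rotation items with
    eight-option response sets and renders them to SVG, simulates
    planned-missingness (synthetic aperture) response data, calibrates and
    scores a two-parameter logistic item response model by marginal maximum
    likelihood, evaluates factor structure via minres factor analysis, a
    Schmid-Leiman transformation and hierarchical omega, and mines
    cross-validated unit-weighted best scales from sparse data.
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
    Matrix,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
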