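Package: leafmorph
Title: Morphometrics of Heteroblastic Leaf Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying leaf shape along heteroblastic series
    (the ordered sequence of leaves from shoot base to tip). Implements
    generalized Procrustes analysis of landmark configurations, elliptical
    Fourier descriptors of leaf outlines (chain-code tracing, Kuhl-Giardina
    harmonic decomposition, first-harmonic normalization), allometric
    regression of leaf subareas, per-trait decomposition into species,
    heteroblasty and species-by-heteroblasty effects, per-node species
    discrimination by leave-one-out linear discriminant analysis, and
    heteroblastic trajectory vectors in a two-dimensional embedding. Includes
    a synthetic leaf-series generator with known ground truth for validating
    every stage, and readers and writers for delimited landmark tables and
    SHAPE-dialect normalized elliptical Fourier descriptor (NEF) files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
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
    MASS,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
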