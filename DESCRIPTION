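Package: vasctum
Title: Hybrid Agent-Based and Continuum Simulation of Vascular Tumor
    Growth and Combination Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates three-dimensional vascular tumor growth and the
    response to a combined Doxorubicin/Trastuzumab treatment at desk
    scale. Tumor cells are spherical agents progressing through a
    five-state stochastic cell cycle; the vasculature is a linked tree
    of cylindrical agents performing VEGF-driven sprouting
    angiogenesis; nutrients, VEGF and the two drugs are scalar fields
    advanced by an explicit (FTCS) reaction-diffusion solver on a
    uniform cubic lattice. Agents and fields are coupled in both
    directions through discrete point and line delta sources. Includes
    synthetic initializers for tumor spheroids and sparse vascular
    networks, treatment scheduling with a capacitor-like drug supply
    factor, parameter-derivation utilities, scenario presets, tidy
    accessors and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
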