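Package: rsvnet
Title: Relative Strength Variability Measures for Weighted Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes relative node strength, Relative Strength Variability
    (RSV) and its sliding-window hierarchical variant (hRSV) for weighted,
    undirected networks such as brain structural connectomes, alongside a
    battery of comparison graph measures (node strength variance, strength
    assortativity, normalised Onnela clustering, routing efficiency and
    random-walk diffusion efficiency). Includes cohort-level proportional
    thresholding, synthetic weighted-network generators for validation,
    low-rank imputation and principal-component extraction of a general
    cognitive factor, and a Gram-Schmidt sequential-residualisation pipeline
    for incremental variance decomposition in ordered regression models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
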