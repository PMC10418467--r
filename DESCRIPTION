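Package: topoqsar
Title: Topological QSAR Modelling of PRMT1 Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Graph-theoretic molecular descriptors and the QSAR models built
    from them for a series of PRMT1 inhibitors with antileukemic activity.
    Parses Kekule SMILES into hydrogen-depleted molecular graphs, computes
    Galvez topological charge indices, Kier-Hall connectivity indices and
    bulk descriptors, evaluates and refits the published linear discriminant
    and multilinear regression models with leave-one-out validation, and
    screens candidate molecules through the discriminant-function and
    predicted-potency activity rules, including pharmacological distribution
    diagrams. All user-facing functions take data frames and return tibbles.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
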