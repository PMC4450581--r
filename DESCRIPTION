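Package: bicm
Title: Maximum-Entropy Null Models for Binary Bipartite Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the Bipartite Configuration Model (BiCM), a degree-constrained
    maximum-entropy null model for binary, undirected bipartite networks, and the
    Bipartite Random Graph (BiRG). Computes bipartite observables on an incidence
    matrix (average nearest-neighbour degrees, Vn and Lambda-n co-occurrence
    motifs, Newman's assortativity coefficient, NODF nestedness and the iterative
    fitness-complexity ranking), their analytic or sampled null expectations, and
    z-scores and similarity against the grandcanonical ensemble, so that trade,
    mutualistic or species-site matrices can be scored for statistically
    significant structure. Includes seed-deterministic synthetic generators
    (hidden-variable, nested, biregular, uniform), tidy and glance methods,
    autoplot methods and a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
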