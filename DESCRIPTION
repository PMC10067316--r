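Package: synkit
Title: Represent, Compare and Cluster Synthetic Chemical Routes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for chemoinformatics operations on synthetic routes
    and reaction networks, such as those predicted by computer-aided
    synthesis planning (CASP) tools. Molecules and chemical equations are
    modelled as identity-bearing value objects whose equality derives from
    canonicalized structures; routes are directed graphs over these nodes
    (the SynGraph model) in bipartite or monopartite form. The package
    reads CASP-style route files, interconverts data formats and graph
    data models, computes route-level descriptors (number of steps,
    longest linear sequence, branching, convergence), measures route
    distances by an exact graph edit distance with fingerprint-based
    chemical substitution costs, and clusters routes with
    silhouette-optimized agglomerative or density-based methods. A seeded
    synthetic-route generator with known-by-construction ground truth
    supports testing end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    parallel,
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
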