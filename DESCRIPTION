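Package: poolnet
Title: Species Co-Occurrence Networks, Modules and Multivariate Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds species co-occurrence networks from site-by-species
    presence-absence data and partitions species into groups by two routes:
    simulated-annealing (spin-glass) modularity maximisation on the unweighted
    network, and partitioning-around-medoids (PAM) clustering of Jaccard
    dissimilarities with gap-statistic selection of the number of clusters.
    The two partitions are compared with a congruence statistic maximised over
    label matchings and tested by permutation, with a multi-response
    permutation test of spatial clustering of species range centroids, and
    with a nest-associate completeness and probabilistic (hypergeometric)
    co-occurrence effect-size analysis. A synthetic-data generator with
    planted group structure, planted spatial clustering and a planted
    host-associate complex makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    clue,
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
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
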