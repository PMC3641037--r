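Package: aflpscape
Title: Phylogeographic Analysis of Dominant-Marker and Mitochondrial Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for landscape-genetic analysis of binary dominant
    markers (AFLP band presence/absence) together with a mitochondrial
    coding alignment. Implements Bayesian admixture clustering with the
    Evanno delta-K statistic for choosing the number of clusters, analysis
    of similarities (ANOSIM) for geographic concordance of clusters,
    distance-based redundancy analysis (partial dbRDA) partitioning genetic
    variation into isolation-by-distance and cluster-subdivision components,
    a quartile-intersection screen for gene-flow barriers and long-distance
    dispersal, Fu's Fs via the Ewens sampling formula with a coalescent
    null, the McDonald-Kreitman test, and a per-locus environmental
    association scan with dual likelihood-ratio and Wald gating. A spatially
    explicit synthetic-data generator provides test data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    vegan,
    mclust,
    geosphere,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
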