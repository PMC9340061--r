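Package: phylassem
Title: Phylogenetic and Functional Community Assembly Inference
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the processes structuring ecological communities from a
    phylogeny, a species-by-trait table, a site-by-species matrix and
    site-level environmental variables. Implements Blomberg's K with
    tip-shuffle permutation tests, standardized effect sizes of mean pairwise
    functional and phylogenetic distance (SES.MPD) under a regional-pool
    tip-shuffle null, Wilcoxon departure tests, and environmental driver
    attribution via collinearity screening, forward stepwise selection and
    exact hierarchical partitioning of regression variance. A synthetic-data
    module simulates ultrametric trees, Brownian and Ornstein-Uhlenbeck
    traits, correlated environmental gradients and communities assembled at
    random, by abiotic filtering or by limiting similarity, so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    phytools,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
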