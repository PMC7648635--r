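Package: vegpersist
Title: Weighted Residence Time and Trait-Based Persistence Analysis for
    Resurveyed Vegetation Plots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing fine-scale species persistence in repeatedly
    surveyed permanent vegetation quadrats. Implements the weighted residence
    time (WRT) persistence index in presence/absence and cover-weighted forms,
    a permutational multivariate analysis of variance (PERMANOVA) on
    Bray-Curtis dissimilarities, mixed-type Gower trait distances with mean
    pairwise functional and phylogenetic diversity, neighbor-joining tree
    utilities, and conditional inference trees relating persistence to plant
    functional traits via rank-based permutation tests. Includes a synthetic
    community time-series generator emulating a multi-site long-term herb
    layer monitoring design, and a config-driven pipeline that runs the full
    analysis sequence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    picante,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
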