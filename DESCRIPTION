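Package: planknet
Title: Community Assembly and Co-Occurrence Network Stability for Amplicon OTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing planktonic microbial community assembly and
    co-occurrence network stability along environmental gradients. Provides
    synthetic OTU-table generators with known ground truth (neutral,
    niche-gradient, dispersal-structured and block-correlated regimes),
    alpha and beta diversity with environmental correlations, canonical
    analysis of principal coordinates (CAP) and PERMANOVA, Sloan neutral
    community model fitting with 95% prediction bands, PER-SIMPER /
    dispersal-niche continuum index (DNCI) inference under constrained null
    models, and Spearman co-occurrence network construction with topology
    metrics and targeted node-removal fragmentation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    MASS,
    stats,
    tools,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
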