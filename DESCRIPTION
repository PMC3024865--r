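Package: fatemapExpr
Title: Lineage-Aware Multi-Tissue Gene Expression Divergence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of multi-tissue expression data in association with a
    developmental fate map. Implements rank-based per-gene expression
    divergence and conservative-gene calling, three gene-set statistics
    evaluated at every node of the fate-map tree (log-scale expression
    distance with a fitted normal null and group-integrated p-values,
    Kolmogorov-Smirnov difference tests with normal-quantile Z integration,
    and Pearson profile correlation), hypergeometric over-representation
    analysis with Bonferroni correction, cross-species comparison of
    significant-module proportions, and a fate-map-structured synthetic data
    generator with planted conserved, divergent and correlated modules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
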