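Package: nichescreen
Title: Connectivity-Map Screening of Germinal-Zone Expression Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-silico pharmacogenomic screening pipeline for neural
    germinal-zone biology. From a probe-level expression compendium of
    subventricular-zone cell populations it builds directional
    differential-expression signatures (fold-change and FDR filtered,
    probe-to-gene collapsed), scores them against a drug-perturbation
    reference database with the two-sided Kolmogorov-Smirnov connectivity
    statistic or a rank-correlation scorer, ranks small molecules by
    target-gene counts, and characterizes hits by protein-target category,
    hypergeometric gene-set enrichment, hierarchical expression clustering,
    and node-capped shortest-path subnetwork extraction over a typed
    interaction graph. A seeded synthetic-data generator emulates the
    statistical structure of the real compendium and drug database so the
    whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
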