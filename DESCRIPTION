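Package: csenet
Title: Core Gene Co-Expression Networks via Centralization Within
    Sub-Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds "core" gene co-expression networks from heterogeneous
    expression compendia by mean-centering every gene within each
    sub-experiment (a group of biological replicates) before estimating
    pairwise association. This centralization step removes
    treatment-, tissue- and batch-driven mean differences that otherwise
    create spurious edges between unrelated but co-regulated genes.
    The package provides four association estimators (Pearson, full-order
    partial correlation, biweight midcorrelation, topological overlap),
    sparsity-controlled and bootstrap-aggregated adjacency construction,
    exact binomial tests for pronounced sub-networks, Fisher and
    two-proportion comparisons of networks, random-walk community
    detection with overlay onto condition-specific networks,
    guilt-by-association functional profiling, and a synthetic-data
    generator with known ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    limma,
    fgsea,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
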