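Package: goscca
Title: Sparse Canonical Correlation Analysis with a Graph-OSCAR Penalty
Version: 0.1.0
Authors@R:
    person("goscca", "developers", email = "goscca@example.org", role = c("aut", "cre"))
Description: Structured sparse canonical correlation analysis (SCCA) using the
    graph-OSCAR (octagonal shrinkage and clustering) penalty, which encourages
    highly correlated features to receive canonical loadings of similar
    magnitude without requiring the sign of pairwise sample correlations to be
    fixed in advance. Provides the iteratively reweighted alternating solver,
    grouping-effect diagnostics with an explicit upper bound on pairwise
    loading gaps, a latent-factor paired-data simulator with sign-swapped
    feature groups, a nested cross-validation protocol for hyperparameter
    tuning, and a command-line interface for fitting, simulating and
    cross-validating from delimited text files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
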