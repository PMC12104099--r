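Package: seqgaps
Title: Multiple Imputation of Gaps in Categorical State Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for handling missing data in univariate categorical
    longitudinal data (life-course state sequences). Implements the MICT
    gap-imputation algorithm and its timing-aware extension (position-specific
    imputation models restricted to a time window), fully conditional
    specification (chained equations) over time points, and variable-length
    Markov chain imputation with context-tree pruning and AIC model selection.
    Also provides missing-data amputation generators (MAR gaps, attrition,
    small samples), timing/duration/sequencing estimands with bootstrap
    variances, Rubin's-rules pooling, and a simulation engine reporting bias,
    coverage and variance with Monte Carlo standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    nnet,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
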