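Package: SigConsensus
Title: Consensus Analysis of Gene Signatures via Co-Occurrence Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates a tested gene signature against a collection of
    previously reported reference signatures drawn from a common biomarker
    space. For every tested gene the number of reference signatures
    containing it is counted, giving an empirical co-occurrence frequency
    distribution; a size-matched randomized-sampling null (with an exact
    Poisson-binomial oracle) provides the expected background distribution.
    Comparison of the two reverse cumulative curves (Kolmogorov-Smirnov
    statistic and per-threshold tail-ratio p-values) selects a co-occurrence
    threshold that dichotomizes tested genes into statistically novel (SN)
    and statistically common (SC) biomarkers. Includes Weibull and sigmoid
    tail fits for null-distribution families, a synthetic-data generator
    with planted SN/SC structure, and report writers for GMT and plain
    symbol-list inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'classify.R'
    'cooccurrence.R'
    'curvefit.R'
    'fixtures.R'
    'geneset-io.R'
    'null-model.R'
    'pipeline.R'
    'synthetic.R'
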