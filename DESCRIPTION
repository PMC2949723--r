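Package: connmap
Title: Connectivity-Map Drug Repositioning from Differential Expression Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested re-implementation of a microarray-to-compound analysis
    chain: rank-stability-trained piecewise-linear normalization against a
    computational naive control pool, floored fold-change and Student t-test
    differential-expression signature extraction, hierarchical clustering
    validation, and rank-based Kolmogorov-Smirnov connectivity scoring of the
    signature against a compound reference database with permutation p-values.
    Includes a synthetic-data generator that plants known up/down-regulated
    probes and known signature mimics and reversers so every stage can be
    checked against ground truth.
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
    withr,
    yaml
Config/testthat/edition: 3
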