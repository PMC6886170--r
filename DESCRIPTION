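Package: phasedeg
Title: Response-Order-Preserving Differential Expression Across
    Heterogeneous Time-Series Samples
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Integrates multiple heterogeneous time-series gene expression
    samples measured under the same perturbation and identifies genes that
    are differentially expressed in common across samples and whose
    response order is preserved.  Single-sample differential calls are
    combined through a permutation test on the gene-by-sample DEG matrix,
    consensus genes are clustered by cosine similarity of concatenated
    profiles (spherical k-means), a per-sample response time is located for
    every cluster by hill climbing on a pooled t-statistic, and clusters
    are greedily arranged into the longest conflict-free response schedule,
    yielding a response phase for every retained gene.  Includes a
    synthetic-data generator with planted response-order structure for
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    optparse
Config/testthat/edition: 3
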