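Package: cellwave
Title: Constrained Pseudotime Ordering and Trend Detection for Time-Course
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs a one-dimensional cell ordering from time-course
    single-cell RNA-seq by extended nearest insertion with a hard
    collection-time block constraint, refined by 2-opt local search, with the
    ordering objective being the aggregated mean squared error of polynomial
    regression over a marker-gene panel.  Includes quality control and
    median-by-ratio normalization for expression matrices, bulk-supervised
    principal component analysis (single cells projected onto bulk-derived
    loadings), a permutation test that "fishes" candidate genes for smooth
    expression trends along the recovered order, a directional
    Kolmogorov-Smirnov caller that composes per-transition calls into
    expression paths over ordered conditions, and a synthetic-data generator
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
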