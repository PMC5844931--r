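Package: circompare
Title: Comparing and Combining Circular RNA Prediction Call Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking and combining back-splice junction call
    sets from circular RNA (circRNA) prediction algorithms. Harmonizes
    heterogeneous BED-like call tables to a common 0-based half-open
    convention, applies read-support and quality filters, classifies
    candidates as RNase R resistant, unchanged or sensitive from
    treated/untreated fold enrichment, and scores pairwise and three-wise
    algorithm complementarity with the iTP/iTN indices and the Complementary
    score (iTP x iTN)^2. Includes mature spliced-length estimation from
    transcript models and a synthetic multi-algorithm experiment generator
    with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
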