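Package: netsubsample
Title: Sensitivity of Global Animal Social-Network Metrics to Sampling
    Effort
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how the number of individuals sampled and the
    number of observations per individual affect global measures of
    animal social networks built under the gambit-of-the-group
    assumption. Provides half-weight and simple-ratio association
    indices from daily co-occurrence records, weighted modularity with
    greedy community detection, day-constrained data-stream permutation
    tests for community structure, bootstrap community assortativity
    (Rcom), a full individuals-by-observations subsampling experiment
    with per-regime summaries and regression analyses, and a synthetic
    fission-fusion roosting-data generator with planted community
    structure for calibration and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
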