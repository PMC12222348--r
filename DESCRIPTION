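Package: reachcong
Title: Reliability of Congruency Effects in Reaching and Release-and-Press Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement and reliability pipeline for reaching and
    release-and-press versions of congruency tasks (flanker, Stroop, Simon).
    Extracts initiation time, movement time, response time, and reach
    curvature from raw trajectories; codes trial-sequence conditions and
    applies a standard exclusion ladder; computes congruency-effect
    difference scores and their descriptive statistics; estimates
    permutation-based split-half reliability with Spearman-Brown correction
    and percentile confidence intervals; decomposes congruency sequence
    effects with 2x2x2 within-subject ANOVAs; and simulates trial-level
    congruency-task data (optionally with raw reach trajectories) under a
    dual-process generative model with known true reliability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2,
    knitr
Config/testthat/edition: 3
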