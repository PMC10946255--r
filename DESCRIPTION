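Package: dmapool
Title: Dynamic Mode Analysis of Biochemical Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Data-driven timescale decomposition of biochemical reaction
    networks. Simulates mass-action kinetic models, applies an extended
    optimal dynamic mode decomposition to locally linearized, inhomogeneous
    deviation dynamics in a sliding time window, and extracts dominant
    exponential decay modes, concentration pools, characteristic time
    intervals, and coherent structures from concentration time series.
    Includes closed-form analytic references for a hierarchical linear
    pathway model used to validate the data-driven pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
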