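Package: comboscreen
Title: Analysis of Dose-Matrix Drug Combination Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for high-throughput dose-matrix (checkerboard)
    drug-combination screens. Normalizes raw plate signal to
    fraction-of-control viability, fits single-agent median-effect and
    four-parameter logistic dose-response models, computes per-well synergy
    surfaces (excess over highest single agent, delta Bliss) and per-pair
    scores (Chou-Talalay combination index, maximal-efficacy beta ratio),
    and runs a two-stage hit-triage workflow with mechanism-of-action class
    aggregation. Ships an in-silico screen simulator with known ground truth
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    broom,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
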