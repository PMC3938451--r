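Package: sraholter
Title: Stroke Risk Analysis of Holter ECG Snips for Atrial Fibrillation Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects manifest atrial fibrillation (AF) and flags risk of
    paroxysmal AF from 1-hour snips of Holter ECG or RR-interval series.
    Implements QRS detection and morphology-based beat classification on
    multi-lead ECG, the heart-rate-variability feature set used by
    complexity-based stroke-risk screening (Poincare SD1/SD2 by principal
    components, normalized RR-difference statistics, extreme-window ratio,
    premature-atrial-complex typing and census, approximate entropy), a
    seedable margin classifier over those features, clock-aligned hour-snip
    segmentation of 20-24 h recordings with pseudonymization, diagnostic
    sensitivity/specificity evaluation including packaged study contingency
    tables, and a fully annotated synthetic Holter generator that provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    e1071,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
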