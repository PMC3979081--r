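Package: fasss
Title: FAt Spondyloarthritis Spine Score and Reader-Reliability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the FAt Spondyloarthritis Spine Score (FASSS), an
    anatomy-based semi-quantitative scoring system for focal fat lesions on
    T1-weighted spine MRI in axial spondyloarthritis. Scores structured
    lesion annotations (not images) over the 23 disco-vertebral units from
    C2/C3 to L5/S1, computes segmental and total scores and longitudinal
    change scores, and provides the accompanying reader-reliability
    toolkit: single-measure absolute-agreement intraclass correlation from
    a two-way model with F-based confidence intervals and qualitative
    banding, Bland-Altman limits of agreement at configurable coverage,
    the smallest detectable change, interval-stratified reliability,
    cumulative-probability plot data, and adjudication rules for flagging
    discrepant change scores. A synthetic two-reader cohort simulator with
    segment-dependent lesion prevalence and configurable reader
    misclassification supports end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
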