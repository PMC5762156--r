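Package: strokelab
Title: Laminar Electrophysiology and Motor-Behavior Analysis for Rodent
    Stroke-Rehabilitation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of optogenetically evoked laminar field
    potentials (component amplitudes and latencies, paired-pulse ratio,
    inverse current-source density by the step method, multi-unit activity
    by sliding RMS), skilled-reaching trajectory kinematics (path length,
    enclosed area, mean speed, smoothness), robotic-platform force-trace
    metrics (retraction time and attempt counts), and classical rodent
    behavioral scores (foot-fault percentage, forelimb-use asymmetry,
    reaching error rate, lesion volume, power analysis). Includes seeded
    synthetic-data generators with known ground truth for every stage and
    a pipeline that runs a whole synthetic cohort end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
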