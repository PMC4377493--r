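Package: connfeed
Title: Connectivity Neurofeedback Simulation and Resting-State Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop simulation of connectivity-based fMRI neurofeedback
    together with the offline resting-state analyses used to evaluate it.
    Provides the online feedback engine (high-pass filtering, trial windowing,
    inter-ROI correlation and baselined scoring), a synthetic multi-subject
    BOLD generator with controllable network correlation structure and a
    reward-responsive virtual subject, ROI-based network analysis (nuisance
    regression, Fisher-z correlation matrices, difference matrices, a
    colored-cell rule with a bootstrap network-pair test, and group
    statistics), and whole-brain voxelwise degree-of-connectivity mapping with
    Monte-Carlo cluster-size correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    RNifti,
    jsonlite,
    readr,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
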