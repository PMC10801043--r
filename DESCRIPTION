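Package: navassess
Title: Analysis of VR Spatial-Navigation Usability Studies with Foot-Motion Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy analysis pipeline for virtual-reality spatial-navigation
    usability studies in which seated participants relocate objects in a
    virtual environment using a foot-motion pad. Computes per-trial spatial
    recall error in polar coordinates (distance r, angular deviation theta)
    with a configurable correctness radius, reduces 100 Hz foot-motion
    telemetry (pitch/yaw tilt) to scalar magnitude series and weighted
    Jaccard encoding-recall similarity, scores the System Usability Scale
    (with the seven-band adjective interpretation) and ITC-SOPI negative
    effects, and runs within-subject group statistics (paired t, Wilcoxon
    signed-rank with tie diagnostics, and trial-level mixed-effects ANOVA
    with participant random intercepts and Satterthwaite degrees of freedom).
    Includes a synthetic cohort generator with known ground truth so the full
    pipeline is testable without access to raw study data.
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
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
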