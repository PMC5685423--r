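Package: perisr
Title: Simulated Peripheral Acuity Experiments with Motion-Based
    Super-Resolution Observers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation pipeline for peripheral visual acuity experiments in
    which a Landolt-C optotype is viewed through an occluding element mask.
    Renders the masked stimulus movies for six target/mask dynamic conditions
    (static, smooth isoeccentric motion, frame-shuffled motion, per-frame mask
    regeneration, mask motion), replaces human subjects with parameterized
    model observers -- including a motion-compensated shift-and-add
    super-resolution observer -- and runs the complete psychophysical
    analysis: 3-down-1-up adaptive staircases, maximum-likelihood fitting of
    the 4AFC logistic psychometric function with nonparametric bootstrap
    confidence intervals, condition contrasts, and two-way repeated-measures
    ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
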