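Package: cpcst
Title: Simulation and Psychometric Analysis of the Continuous Performance
    Critical Stability Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for the Continuous Performance Critical
    Stability Task (cpCST), a closed-loop visuomotor paradigm in which a
    participant stabilizes an unstable stimulus whose divergence rate is set
    by a gain parameter (lambda). Provides a discrete-time simulator of the
    unstable plant driven by synthetic participant controllers (delayed
    proportional feedback with motor noise and attentional lapses), the
    adaptive calibration phase that estimates the motor stability threshold,
    crash excision with shape-preserving (PCHIP) reconstruction, the
    dynamic-time-warping instantaneous reaction time (iRT) metric, and a
    psychometric evaluation pipeline: bootstrap split-half reliability with
    the Spearman-Brown correction, temporal-efficiency stability curves,
    Steiger's Z for dependent correlations, flanker-task comparison metrics,
    and predictive-validity regressions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
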