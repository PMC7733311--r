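Package: gazexpert
Title: Classifying Art Experts from Eye-Movement Fixation Patterns
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for distinguishing art experts from laymen using
    oculomotor data recorded while viewing paintings. Regions of interest
    (ROIs) are discovered by fitting a bivariate Gaussian mixture to fixation
    positions with the EM algorithm, choosing the number of components by the
    Bayesian information criterion. Per-subject, per-ROI fixation counts and
    mean fixation durations become features, optionally standardized by one
    of several z-score schemes; features are ranked by two-sample t-statistic
    or chosen by sequential forward selection, and subjects are classified by
    k-nearest neighbours or kernel support vector machines under
    leave-one-subject-out cross-validation. A synthetic-cohort generator with
    known ground truth supports power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    mvtnorm,
    quadprog,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
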