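Package: dynFNC
Title: Dynamic Functional Network Connectivity States from Component Time Courses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimation of time-varying functional network connectivity from
    independent-component time courses: motion (framewise displacement)
    regression, detrending, despiking and band-pass filtering; whole-scan
    static connectivity with FDR-controlled group contrasts; Gaussian-tapered
    sliding-window connectivity with an L1-regularised (graphical LASSO)
    covariance estimator; k-means (L1 distance, median centroids) estimation
    of discrete connectivity states with elbow-based model selection;
    per-subject state occupancy statistics (mean dwell time, fraction of
    time, transition matrices) with bootstrap stability screening of group
    differences; and linear support-vector-machine validation of the sliding
    window width and group classification under leave-one-out
    cross-validation. A Markov-switching multivariate Gaussian cohort
    simulator with known state structure supports end-to-end testing and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    Rcpp,
    signal,
    e1071,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: FunctionalConnectomics, TimeCourse, Clustering, Classification,
    StatisticalMethod
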