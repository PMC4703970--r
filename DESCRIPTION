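Package: netcpd
Title: Bootstrap Change-Point Detection for Correlation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distribution-free detection of change points in the correlation
    (covariance) structure of multivariate time series, as used to study
    evolving correlation networks of stocks or brain regions. A matrix-distance
    scan statistic (squared Frobenius norm, maximum norm, a Gaussian
    likelihood-ratio statistic, or a vech quadratic form) compares the
    empirical covariance before and after each candidate time point; its null
    distribution is simulated by an i.i.d. column bootstrap, or by an
    autoregressive sieve bootstrap when the series are autocorrelated.
    Multiple change points are found by recursive binary segmentation.
    Includes the analytic null expectation of the Frobenius scan statistic for
    Gaussian data, synthetic-data generators with block-exchangeable covariance
    designs, power and calibration experiments, Durbin-Watson autocorrelation
    diagnostics with AR order selection, and thresholded-network export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
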