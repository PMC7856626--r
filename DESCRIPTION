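Package: pqxinar
Title: Poisson-Quasi-Xgamma Distribution and INAR(1) Models for
    Over-Dispersed Count Time Series
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling over-dispersed count data and count time
    series. Implements the Poisson-quasi-xgamma (PQX) distribution (exact
    probabilities, moments, shape classification, mean parametrization and
    random generation), parameter estimation for iid samples by maximum
    likelihood, method of moments and an EM algorithm, and the first-order
    integer-valued autoregressive process with PQX innovations (INARPQX(1))
    together with Poisson, geometric, negative binomial and Poisson-Lindley
    innovation families. Provides conditional maximum likelihood and
    Yule-Walker estimation, information criteria based model comparison,
    Pearson residual diagnostics, a test for over-dispersion against the
    Poisson INAR(1) null, one-step-ahead forecasting, and a seeded
    replication harness for simulation studies of estimator performance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
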