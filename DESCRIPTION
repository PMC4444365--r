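Package: oliverate
Title: Population Dynamics of the Olive Fruit Fly from Trap-Monitoring Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse monthly trap-monitoring time series of the olive
    fruit fly (Bactrocera oleae). Builds flies-per-trap-per-day (FTD) abundance
    indices and their log-scale monthly transform (MFT), computes the rate of
    population change (R-function), and diagnoses the order of density-dependent
    feedback with autocorrelation and partial rate correlation functions (PRCF).
    Fits generalized least squares models with ARMA(p,q) residual correlation and
    stratified or covariate-proportional variance structures by ML or REML, ranks
    candidate structures by BIC with a parsimony tie-break, and corrects
    attenuation of the density-dependence estimate caused by sampling error using
    simulation-extrapolation (SIMEX). A synthetic-data generator reproduces the
    statistical structure of field monitoring series so the whole pipeline can be
    validated by parameter-recovery simulation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
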