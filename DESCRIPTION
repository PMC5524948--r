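Package: glucodyn
Title: Chaotic Time-Series Analysis and Regime-Switching Forecasting for
    Continuous Glucose Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for short-term forecasting of continuous glucose
    monitoring (CGM) traces from their nonlinear dynamics.  Glucose series
    are characterised by delay-embedding diagnostics (average mutual
    information, Cao's embedding dimension, Grassberger-Procaccia
    correlation dimension, largest Lyapunov exponent, recurrence plots),
    embedded in phase space via Takens delay vectors, and forecast 30 or
    60 minutes ahead with phase-space autoregressive models: linear AR,
    additive AR, neural-network AR, self-exciting threshold AR (SETAR),
    and logistic smooth-transition AR (LSTAR).  Predictions are scored
    numerically (RMSE, MAE, MAPE) and clinically (continuous glucose
    error-grid analysis).  Glycemic-variability indices (SD, CV, J-index,
    MAGE, CONGA, MODD, GVI, PGS) and hypo-/hyper-glycemia risk indices
    (LGI, HGI) are reported per landmark interval.  A seeded synthetic-CGM
    generator with controllable risk strata and canonical chaotic
    benchmark systems support validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    mgcv,
    nnet,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
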