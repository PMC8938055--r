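Package: rankpls
Title: Partial Least Squares Regression with Rank-Correlation Loading Weights
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Partial least squares regression for ordinal (ranked) responses
    under multicollinearity. The NIPALS loading weights can be replaced by any
    of eight rank-association measures (Spearman's rho, Kendall's tau-A/B/C,
    Somers' D, Goodman-Kruskal's tau and gamma, Theil's U), giving a family of
    PLS variants suited to rank-scale data. Includes filter-based variable
    selection (loading weights, regression coefficients, significance
    multivariate correlation), AIC model comparison, Monte-Carlo 70:30
    cross-validation with linear discriminant analysis on the component
    scores, and a latent-Gaussian generator of synthetic ranked datasets for
    simulation studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
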