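Package: kebandwidth
Title: Kernel Equating with Data-Driven Bandwidth Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for observed-score kernel equating of discrete test-score
    distributions. Implements Gaussian-kernel continuization with moment
    preservation, log-linear (polynomial Poisson) presmoothing with AIC/BIC
    model selection, equipercentile equating under the equivalent-groups and
    NEAT post-stratification designs, analytical and bootstrap standard
    errors of equating, and six data-driven bandwidth selection methods
    (penalty, Silverman's rule of thumb, double smoothing, likelihood
    cross-validation, leave-one-out cross-validation, and penalized
    leave-one-out cross-validation). A simulation engine generates
    realistic score data from beta / beta-mixture latent traits through a
    Gaussian copula and evaluates the selectors by mean squared error,
    per-score standard error, and percent relative error of moments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
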