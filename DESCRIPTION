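Package: sdmniche
Title: Presence-Background Distribution Models and Range-Wide Niche Breadth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing specialist-generalist niche theory with
    presence-background species distribution models. Implements a
    maximum-entropy model with L1 regularization (linear, quadratic,
    product, hinge and categorical-indicator features; no threshold
    features), Gaussian-kernel sampling-bias weighting surfaces,
    occurrence filtering and spatial thinning, two-stage environmental
    variable screening, k-fold cross-validation with presence-background
    AUC, jackknife estimates of regularized training gain, Levin's
    standardized niche breadth with random-presence null models, and
    univariate response-curve statistics (standardized area under the
    curve as total resource exploitation, maximum height as peak
    performance) together with a classifier for the standard and
    alternative conceptual niche models. A virtual-species simulator
    generates autocorrelated landscapes, specialist/generalist species
    with prescribed response curves, and biased noisy presence samples
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
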