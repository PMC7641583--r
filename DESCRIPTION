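Package: morphosense
Title: Precision Limits of Morphogen Gradient Readout
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state models and fundamental sensing limits for the two
    canonical mechanisms of morphogen gradient formation: direct transport
    through cytonemes and synthesis-diffusion-clearance (SDC). Provides
    closed-form mean profiles, correlation times and readout precision for
    both mechanisms, a discrete-hopping simplification of SDC, the
    DT-to-SDC precision ratio with its profile-lengthscale crossover, and
    classification of morphogens by predicted mechanism. Includes exact
    event-driven (Gillespie) simulators, a deterministic cytoneme transport
    integrator and lattice covariance solvers that validate every closed
    form, plus reproducible figure-style datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2,
    knitr
Config/testthat/edition: 3
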