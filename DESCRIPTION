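Package: nhppsim
Title: Simulation of Non-Homogeneous Poisson Point Processes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact simulation of event times from one-dimensional
    non-homogeneous Poisson point processes (NHPPPs) for discrete-event
    and statistical simulation. Implements the three classical sampling
    schemes (thinning/acceptance-rejection, time transformation through
    the inverse cumulative intensity, and Poisson-count order statistics),
    closed-form samplers for constant, piecewise-constant, linear and
    log-linear intensities, sampling conditional on a minimum number of
    events via truncated Poisson counts, automatic piecewise-constant
    majorizer construction for thinning, reproducible random-number
    streams with antithetic support, count- and time-distribution
    validation metrics (bias, coverage, chi-squared goodness of fit,
    Wasserstein-1 distance), and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
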