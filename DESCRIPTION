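Package: fracpredprey
Title: Fractional-Order Eco-Epidemic Prey-Predator Dynamics with Neural
    Surrogates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a three-compartment eco-epidemiological system
    (susceptible prey, infected prey, predator with hunting cooperation)
    under a Caputo fractional-order derivative, using the
    Adams-Bashforth-Moulton predictor-corrector on a uniform grid with
    full-memory quadrature weights. A shallow feedforward network
    (one input, ten tanh hidden units, three linear outputs) is fitted to
    the reference trajectories with a from-scratch scaled conjugate
    gradient optimizer, min-max normalization, a seeded 75/10/15
    train/validation/test split and validation-based early stopping.
    Reports split-wise mean squared error, gradient norms, absolute-error
    curves against the reference solution, error histograms and
    regression statistics, exportable as JSON and CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
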