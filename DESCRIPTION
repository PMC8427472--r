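Package: alchemble
Title: Ensemble Alchemical Relative Free-Energy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ensemble-based analysis of alchemical relative
    binding free-energy calculations. Generates synthetic per-lambda-window
    dU/dlambda time series and reduced-potential matrices with analytically
    known free energies, estimates free-energy changes by thermodynamic
    integration (with stochastic-integral error propagation) and by a
    multistate Bennett acceptance ratio (MBAR) solver with asymptotic
    errors, quantifies uncertainty across replica ensembles, runs a minimal
    replica-exchange solute-tempering sampler on analytic one-dimensional
    potentials, and computes benchmark accuracy and bias statistics
    (sign-rearranged MUE/MSE/RMSE, regression, bootstrap standard
    deviations, binned underestimation analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
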