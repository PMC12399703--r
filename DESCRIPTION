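Package: dinnr
Title: Disease-Informed Neural Networks for the SIR Inverse Problem
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the transmission and recovery rates of the
    SIR compartmental epidemic model directly from noisy incidence time
    series with physics-informed neural networks. Provides a Runge-Kutta
    forward simulator and synthetic noisy-data generator, a one-hidden-layer
    "simple" disease-informed network trained by multistart bounded
    nonlinear optimization against finite-difference ODE residuals, and a
    full multilayer perceptron trained by Adam on a composite loss of data
    misfit, initial-condition misfit and autodifferentiated ODE residuals,
    in which the epidemic parameters are learned jointly with the network
    weights. Includes a repeated-initialization robustness study with
    learning-curve confidence bands, broom-style tidiers and ggplot2
    visualizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
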