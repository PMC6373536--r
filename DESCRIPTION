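Package: pushpull
Title: Diffusion-Model Analysis of Approach-Avoidance Joystick Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for trial-level reaction-time and choice
    data from approach-avoidance joystick tasks with angry and happy facial
    expressions. Generates synthetic experiments from a two-boundary Wiener
    diffusion process, applies the standard exclusion rules (response-time
    trimming, high-error participant exclusion), estimates EZ-diffusion
    parameters (drift rate, boundary separation, non-decision time) per
    participant and design cell in closed form, quantifies evidence for
    ANOVA-style model terms with Bayes factors (BIC approximation for mixed
    designs, exact JZS integral for one-sample t tests) and highest-density
    intervals for standardised effect sizes, models accuracy with binomial
    generalised estimating equations and reaction times with ex-Gaussian
    regression, and assesses model fit by posterior-predictive simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
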