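Package: stridepower
Title: Validity Analysis of Foot-Mounted Running Power Meters Against
    Force-Platform and Metabolic References
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to validate wearable running power meters (footpods) against
    laboratory reference systems. Implements the reference biomechanics chain
    (ground contact detection from vertical ground reaction force, recursive
    integration of centre-of-mass motion, external mechanical power, mechanical
    cost of running, McMahon-Cheng leg spring stiffness, breath-by-breath
    oxygen-uptake processing and net mechanical efficiency), distance-based
    alignment of 1 Hz device records with force-platform passages, and a
    Bayesian agreement framework: linear and linear mixed models with
    metric-specific priors sampled by MCMC, Bayes factors by bridge sampling,
    intraclass correlation, Jeffreys correlation tests, Bland-Altman limits of
    agreement and a linear power-correction function. A spring-mass session
    simulator with known ground truth exercises the whole pipeline end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
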