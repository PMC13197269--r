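Package: stemwater
Title: Stem Water Content Dynamics from Frequency-Domain Reflectometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing continuous stem water content in trees and
    palms measured with frequency-domain reflectometry (FDR) sensors.
    Converts dielectric permittivity and stem temperature into
    temperature-corrected volumetric water content, summarises diurnal and
    seasonal storage and discharge dynamics, classifies hydraulic strain
    from relative diurnal discharge capacity, detects soil-moisture
    breakpoints in stem hydration with penalized-spline derivatives, and
    contrasts plant functional groups with t- and permutation tests. A
    synthetic scenario generator with known ground truth makes the full
    pipeline testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
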