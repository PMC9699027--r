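Package: mcrkin
Title: Soft Multivariate Curve Resolution and Degradation Kinetics for NIR Aging Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying long-term drug degradation from near-infrared
    spectra of intact tablets and pure substances. Implements a soft
    multivariate curve resolution engine (alternating least squares with
    non-negativity, closure, fixed spectra and fixed concentrations),
    closed-form sequential two-step first-order kinetics with rate-constant
    estimation (including joint tablet/substance fits sharing the first-stage
    constant and bounded adjustment of uncertain sample ages), a multi-step
    analysis pipeline that resolves the degradation subsystem of blister-packed
    tablets, and a synthetic spectra generator with known ground truth for
    validation studies. All user-facing functions take and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
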