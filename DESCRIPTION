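Package: cargotug
Title: Stochastic Simulation and Track Analysis of Bidirectional Cargo
    Transport by Opposite-Polarity Motor Teams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the tug-of-war between plus-end directed
    kinesin (KIF16B) and minus-end directed dynein-dynactin-BICD2N (DDB)
    motor teams pulling on a shared membrane cargo.  Provides a Gillespie
    stochastic stepping simulator of vesicles driven by mixed motor teams
    on a multi-lane microtubule lattice (Hookean motor springs, force- and
    ATP-dependent stepping, Bell-type detachment, inactive and diffusive
    motor classes, Metropolis cargo relaxation), a simulated-annealing
    change-point segmentation of position-time tracks into
    constant-velocity runs and pauses, a synthetic track generator with
    known ground truth, and a weighted-statistics layer (weighted ECDF and
    two-sample Kolmogorov-Smirnov test, distance-weighted pause
    frequencies, Bonferroni correction, track classification into minus,
    plus, reversal and stationary tracks).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
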