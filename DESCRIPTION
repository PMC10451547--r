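Package: kinpot
Title: Kinetic Potentiometry for Peroxyl-Radical Antioxidant Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for kinetic-potentiometry
    antioxidant assays based on thermal peroxyl-radical generation (AAPH).
    Provides a forward simulator of the initiation / recombination /
    inhibition reaction scheme (full stiff ODE and quasi-steady-state
    modes), a Nernstian log-radical electrode model, detection of the
    induction period from the potential-curve inflection and the derived
    antiradical capacity, extraction of inhibition rate constants from
    semilogarithmic consumption curves measured with a
    ferricyanide/ferrocyanide mediator cell, and area-above-Exp(dE)
    capacity statistics by the initial-rate and fixed-time methods.
    Includes a seeded synthetic-experiment generator and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    signal,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
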