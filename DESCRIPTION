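Package: bombusforage
Title: Bumblebee Colony Dynamics with Interchangeable Foraging Handling-Time Engines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A desk-scale agent-based simulator of bumblebee (Bombus) colony and
    population dynamics driven by nectar and pollen foraging economics on a
    patchy landscape. Foraging-trip durations combine round-trip flight time
    with a handling-time engine: either the mechanistic Harder-regression
    engine (access and ingestion times from corolla depth, glossa length and
    bee weight, inflated by patch depletion and capped at a maximum) or a
    fixed handling time divided by the patch filling level. Includes three
    per-second foraging mortality hazards, a seeded synthetic resource-poor
    landscape generator, a 19-scenario experiment grid crossing mortality
    models with fixed handling times, trip-count-weighted duration summaries
    and end-of-year hibernating-queen censuses, with tidy tibble outputs,
    ggplot2 plots and broom-style tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
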