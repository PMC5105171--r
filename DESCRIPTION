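Package: co2pause
Title: Diagnostics of the Atmospheric CO2 Growth Rate and the Terrestrial
    Carbon Sink
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to diagnose changes in the growth rate of atmospheric CO2
    from the behaviour of the terrestrial carbon sink. Implements a
    first-principles light-use-efficiency model of gross primary production
    (coordination and least-cost hypotheses), a photosynthesis-dependent
    ecosystem respiration model with an analytic preindustrial equilibrium
    solve, the closed-form sensitivity of photosynthesis to atmospheric CO2,
    a linear one-box sink model of the CO2 growth rate with structural-change
    residual testing, Mann-Kendall/Sen trend estimation, singular spectrum
    analysis with IAAFT surrogate uncertainty, and single-driver detrending
    attribution experiments. A synthetic-forcing generator with known trends
    and sink parameters makes the full pipeline runnable and testable without
    external data.
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
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
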