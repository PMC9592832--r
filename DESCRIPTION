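Package: palyburden
Title: Life-Table Modelling of Productivity-Adjusted Life Years Lost to
    Uncorrected Presbyopia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic life-table pipeline for estimating the
    productivity burden of uncorrected and under-corrected presbyopia in
    low- and middle-income countries. Age cohorts of working-age cases are
    followed in annual cycles to retirement; person-years are discounted,
    weighted by a productivity index built from presenteeism and
    absenteeism, and the resulting productivity-adjusted life years (PALYs)
    lost are valued in current US dollars through employment ratios and GDP
    per capita. Includes validated CSV readers for prevalence, economic and
    mortality panels, a deterministic scenario engine for one-way
    sensitivity analysis, a seeded synthetic-data generator emulating
    GBD/World Bank/ILO-style inputs, table renderers, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    tools,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
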