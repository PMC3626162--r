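Package: scattar
Title: Navigate Health Financing Evidence with Context-Matched Scattar Plots
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for synthesising and navigating the evidence on health
    financing mechanisms in low- and middle-income countries. Stores a
    database of studies scored qualitatively for the impact of seven
    financing mechanisms on five health-system goals, matches a user's
    country to the countries studied via eleven min-max normalised
    indicators and a rescaled Euclidean distance, and lays out every study
    as a colour-, shape- and radius-coded dot in a seven-sector polar
    "scattar" plot rendered to SVG. Includes seeded synthetic generators
    for evidence databases and indicator tables, tabular query and
    summary utilities, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
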