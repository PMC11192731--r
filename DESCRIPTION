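Package: lifespanineq
Title: Lifespan Inequality and Polarization Indicators from Abridged Life Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the standard battery of lifespan inequality and
    polarization indicators from abridged period life tables: life
    expectancy, variance, standard deviation, interquartile range, Gini
    and absolute Gini, the generalized entropy family (mean log
    deviation, Theil, GE(2)), life disparity (e-dagger), Keyfitz's
    entropy, and Duclos-Esteban-Ray polarization in absolute and
    relative form, for the total population and for survivors to age
    15. Provides additive within/between decomposition of generalized
    entropy indices for weighted country groups, a Siler-hazard
    simulator of realistic abridged life tables, readers and writers
    for common life-table CSV layouts, and a batch pipeline emitting a
    country-year-sex panel in a fixed dataset schema.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
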