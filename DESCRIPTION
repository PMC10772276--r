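Package: deutrace
Title: Deuterium-Tracing Analysis of Reductive Dehalogenation Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse deuterium-labelling activity assays for
    reductive dehalogenases at unit mass resolution. Provides a forward
    model of mass isotopologue envelopes for halogenated product ions, the
    deuteration-degree statistic DD1 = B1/(A1+B1) on the first isotopologue
    peak pair with an optional natural-abundance correction, assay mixing
    and enzyme-turnover arithmetic (nkat per cell, molecules per second per
    cell and per protein), paired t-tests over consecutive time points, a
    two-compartment cytoplasmic water-exchange model with an apparent
    H-over-D preference factor, least-squares recovery of the exchange rate
    and preference factor from DD1 time courses, and a synthetic peak-table
    generator emulating triplicate GC-MS measurements for whole-cell and
    crude-extract assay conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    readr,
    ggplot2
Config/testthat/edition: 3
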