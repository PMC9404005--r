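Package: logdqsrr
Title: Apparent Octanol/Water Distribution Coefficients from
    Reversed-Phase LC Retention via Cascaded QSRR Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines apparent n-octanol/water distribution coefficients
    (log D) of weakly and strongly ionized compounds from ion-suppression
    (IS-RPLC) and ion-pair (IP-RPLC) reversed-phase liquid chromatography
    retention data. Provides retention-factor computation with double-point
    retention-time correction, linear solvent strength (LSS) extrapolation of
    log k to 100 percent aqueous mobile phase, the monoprotic-acid ionization
    correction converting log P to log D at a given pH, cascaded quantitative
    structure-retention relationship (QSRR) model building by ordinary least
    squares on solvation descriptors (net static charge, hydrogen-bond acidity
    and basicity), external validation reporting, and a synthetic-data
    generator for parameter-recovery testing. Ships a 73-compound reference
    descriptor table as a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
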