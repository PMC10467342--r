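Package: natzone
Title: Reaction-Transport Modelling and Niche Mapping of the Sediment
    Nitrate-Ammonium Transition Zone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state one-dimensional reaction-transport modelling of
    porewater oxygen, nitrate and ammonium in marine sediments with an
    explicit anammox pathway; detection of the nitrate-ammonium transition
    zone (NAT) from concentration profiles; permutation tests for the
    confinement of depth-resolved taxon abundances to that zone; weighted
    least-squares calibration of kinetic and transport parameters against
    observed profiles; and seeded generators for synthetic porewater and
    community data. Tabular (tibble) interfaces throughout, with broom-style
    tidiers and ggplot2 autoplot methods.
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
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
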