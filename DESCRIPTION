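Package: stratmed
Title: Vertical Stratification and Causal Mediation Analysis for Forest-Edge Butterfly Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing vertical stratification of fruit-feeding
    nymphalid butterflies sampled with paired canopy/understory bait traps at
    forest edges. Implements species canopy probabilities, the delta-edge index
    and sign G-tests with the standard sensitivity filters; a joint Bayesian
    structural-causal mediation model (forest edge acting on canopy capture
    through log-light difference, temperature difference and species forest
    canopy tendency) fitted with JAGS, with missing abiotic covariates handled
    by a harmonic AR(1) state-space block and missing species tendencies by a
    tribe-level hierarchy; and a potential-outcomes effect decomposition (light,
    temperature, species-composition, natural direct, total causal and edge
    effects) computed with common random numbers. A synthetic-data generator
    with known ground truth supports end-to-end testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
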