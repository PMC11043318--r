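Package: lupsma
Title: Population Pharmacokinetic-Pharmacodynamic Modelling of 177Lu-PSMA
    Radioligand Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation tools for a five-compartment population
    pharmacokinetic model of the radioligand [177Lu]Lu-PSMA-I&T with saturable
    salivary-gland binding, allometric and tumor-volume covariate effects and a
    structural decline of tumor uptake over treatment cycles, coupled to a
    prostate-specific antigen (PSA) turnover model with direct and
    effect-compartment-delayed drug effects. Includes virtual-population trial
    simulation of clinical dosing regimens, synthetic SPECT/PSA dataset
    generation in NONMEM-style event format, individual empirical-Bayes (MAP)
    and naive-pooled parameter estimation, tumor time-integrated-activity
    exposure metrics and linear exposure-response threshold analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
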