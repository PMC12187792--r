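Package: phytoaccum
Title: Bioaccumulation Indices and Multivariate Screening for Plant
    Biomonitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for soil-plant bioaccumulation surveys: robust element
    summaries (MAD, RSD), bioconcentration factors, aluminium-normalized
    enrichment factors with a six-class enrichment scale, shale-normalized
    rare-earth patterns with cerium anomalies by geometric extrapolation,
    nutrient stoichiometry with N/P limitation flags, Spearman screening
    of frond chemistry against substrate chemistry and site factors, and
    Ward clustering on correlation distances with Newick export. Includes
    a fully seeded synthetic-data generator emulating a multi-site fern
    frond survey (log-normal concentrations, bedrock-stratified shifts,
    coherent rare-earth elements, configurable frond-substrate coupling
    and injectable cerium anomalies) so every stage of the pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
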