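Package: surfvoc
Title: Microbial Biomass and Chemical Signatures of Wet Household Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Links surface-borne microbial biomass to the volatile and soluble
    chemistry of periodically wet household surfaces (kitchen sinks, shower
    stalls). Implements dynamic flux-chamber estimation of VOC emission rates
    from PTR-TOF-MS concentration time series (steady-state averaging,
    abundance filtering, blank subtraction, area normalisation), qPCR
    gene-copy processing with explicit below-detection policies, linear
    biomass-to-emission yield regression, a single-compartment steady-state
    indoor box model with fixture-geometry adjustment factors, and MS/MS
    molecular networking with modified-cosine spectral alignment and
    source-partition summaries. Seeded synthetic-data generators emulate the
    statistical structure of every input so the full pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    igraph,
    deSolve,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
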