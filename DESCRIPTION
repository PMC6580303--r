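Package: otterphen
Title: Phenology and Demographics of Mistargeted Shark-Otter Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing mistargeted predator-prey interactions from
    wildlife surveillance records, centred on white shark bites to southern
    sea otters. Implements circular (day-of-year) kernel density and
    cumulative-distribution estimation for event phenologies, contingency
    and bootstrap inference for demographic risk factors in live-stranding
    records, and a date-perturbing bootstrap that estimates the core 80%
    seasonal window of shark-bitten strandings per tri-annual period and
    the long-term advance of its median date. A synthetic-data generator
    with known ground truth supports end-to-end testing without access to
    the underlying surveillance archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
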