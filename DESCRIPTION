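Package: voyagenet
Title: Vessel Movement Networks and Biofouling Introduction-Pathway Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying marine non-native species
    introduction pathways from vessel-tracking (AIS) data. Position
    streams are cleaned to hourly resolution, classified into stationary
    and underway behaviour, clustered into anchorage nodes within a
    coastal band, and linked into a directed port-call network. Hull
    Wetted Surface Area (WSA) is estimated per vessel from class-specific
    power-law regressions, the Denny-Mumford small-craft formula, or a
    tender constant, and combined with movement behaviour into per-class
    and per-location introduction threat factors. A synthetic fleet
    simulator with a ground-truth event log makes every stage testable
    without access to confidential tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    purrr,
    lubridate,
    rlang,
    withr,
    geosphere,
    igraph,
    jsonlite,
    mgcv,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
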