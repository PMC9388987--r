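Package: vaxflow
Title: Stochastic Queue-Network Simulation of Vaccination Clinics
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Discrete stochastic queue-network simulation of patient flow
    through COVID-19 vaccination sites. Models mass-vaccination hubs
    (Entrance, Registration, Assessment, Vaccination, Observation with a
    parallel dose-preparation queue and walking lags between stations) and
    smaller general-practice clinics (Registration, Vaccination,
    Observation), with appointment-driven arrivals, no-shows, adverse
    post-vaccination reactions, and seat-limited observation. Provides the
    published baseline scenarios, what-if sweeps over arrival load and
    staff shortages, an appointment-calibration search, and queue
    performance metrics (processing-time percentiles, staff utilisation,
    daily throughput) pooled over replications.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
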