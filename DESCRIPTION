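Package: fivetiers
Title: Tiered Individual-Level Exposure Metrics for Ambient Air Pollutants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models five nested tiers of daily individual-level exposure
    metrics for ambient fine particulate matter (PM2.5), elemental carbon
    (EC), nitrogen oxides (NOx) and carbon monoxide (CO): residential
    outdoor concentrations, residential indoor concentrations from a
    dynamic mass-balance infiltration model driven by a mechanistic
    residential air-exchange-rate model, personal outdoor concentrations
    from GPS tracks matched to hourly concentration fields, microenvironment-
    weighted exposures, and accelerometer-driven inhaled doses normalised by
    body surface area. Each metric is split into background, on-road and
    total components. Includes GPS-based microenvironment classification,
    accelerometer-based physical-activity and minute-ventilation estimation,
    and a fully reproducible synthetic-study generator so the whole pipeline
    can run end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
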