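Package: wetflux
Title: Air-Water CO2 Fluxes and Annual Carbon Transport in Seasonal Wetlands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes air-water CO2 fluxes for inland and transitional waters
    from routine monitoring data. Speciation of the carbonate system from the
    pH-total alkalinity pair (NBS scale, estuarine dissociation constants),
    gas-transfer velocities from daily wind with interchangeable k600
    parameterizations, monthly-to-daily interpolation with explicit hydroperiod
    gaps, annual areal fluxes, and remote-sensing driven up-scaling of areal
    fluxes to regional annual carbon transport. Includes a seeded synthetic-data
    generator that emulates Mediterranean seasonal wetlands (winter flooding,
    summer dry-down, strong CO2 super-saturation cycles) so the full pipeline is
    testable without field data.
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
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    tiff
Config/testthat/edition: 3
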