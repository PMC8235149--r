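Package: warabandi
Title: Irrigation Scheduling Under Rotational Water Turns with FAO-56
    Evapotranspiration and Root-Zone Water Balance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision-support toolkit for scheduling flood irrigation on
    farms served by a fixed rotational water-turn allocation (Warabandi).
    Computes daily grass reference evapotranspiration (ET0) with the FAO-56
    Penman-Monteith equation from temperature, humidity and wind records,
    maps calendar dates to stage-dependent crop coefficients (Kc) to obtain
    crop evapotranspiration (ETc), maintains a root-zone soil-water
    depletion balance with the readily-available-water irrigation trigger,
    and aligns forecast irrigation need to the farmer's water-turn calendar,
    converting recommendations into depth, volume, duration or acre-inch
    units. Includes a seeded synthetic season generator (hot semi-arid
    weather and hourly soil-moisture telemetry), season simulation under
    demand-driven versus every-turn policies, and water-use and yield
    comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
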