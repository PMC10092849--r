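Package: vegtherm
Title: Attribution of Vegetation Cover Effects on Land Surface Temperature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Observation-style attribution of the net warming or cooling
    effect of vegetation cover on land surface temperature (LST) from
    geostationary-style 15-minute LST records. Computes the median morning
    warming rate d(LST)/dt, bins pixels by long-term soil moisture and
    shortwave radiation for space-for-time conditional regressions of the
    rate on fraction of vegetation cover, diagnoses mechanisms through
    energy-dissipation efficiency and surface-albedo sensitivity, and
    accounts for interannual LST change per 1% greening across the tropics
    including the dryland reduction of net vegetal cooling. Includes a
    synthetic satellite-scene generator with planted parameters so every
    stage is testable by parameter recovery without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
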