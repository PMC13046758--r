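Package: heattract
Title: Hourly Heat-Stress Fields on a Fine Grid with Census-Tract Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds hourly heat-stress exposure surfaces (Heat Index,
    Liljegren wet-bulb globe temperature, mean radiant temperature and the
    UTCI polynomial approximation) on a fine reference grid by combining
    daily temperature and dew-point constraints with the diurnal shape of a
    coarser hourly reanalysis, interpolating ancillary meteorology and solar
    radiation with a four-neighbour inverse-distance scheme, and aggregating
    the resulting cell-hour fields to administrative (census-tract) polygons
    with area and population weights. Includes a synthetic-scenario
    generator that emulates every input product, a station-based validation
    harness (bias, RMSE, correlation with station-hour-weighted pooling),
    and Parquet output in the published tract-hour schema.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    arrow,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
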