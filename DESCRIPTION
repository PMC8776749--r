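Package: gaezplus
Title: Update Gridded Crop Statistics to 2015 with Country-Level Ratios and
    Monthly Crop Calendars
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Updates circa-2010 global 5-arcminute gridded crop harvested
    area and production to 2015 using country-level FAOSTAT change ratios,
    derives yields, and disaggregates annual harvested area into monthly
    gridded physical cropland area by crop, subcrop and production system
    (irrigated/rainfed) using MIRCA2000-style crop calendars. Includes the
    GAEZ/FAOSTAT/MIRCA crop concordances, cell-area capping with removal
    orders, special-case country registries (country splits, no-data
    islands, disputed areas), a synthetic miniature-world generator with
    ground truth for recovery testing, and zonal aggregation/regression
    validation tools. Raster I/O covers striped float32 GeoTIFF and
    compressed 12-layer NetCDF with the published naming conventions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    ncdf4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
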