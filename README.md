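# gaezplus

Updating global gridded crop statistics with country-level change ratios,
and disaggregating them into monthly cropland area.

## What it does, and for whom

Gridded global crop datasets — harvested area, production and yield per
crop and production system (irrigated/rainfed) at 5-arcminute resolution —
lag reality by years because rebuilding them is expensive. A pragmatic
refresh keeps the sub-national spatial pattern of a circa-2010 gridded base
and scales every cell by the *national* change observed in FAOSTAT-style
country statistics. `gaezplus` implements that production pipeline for
researchers in global hydrology, land-surface and integrated-assessment
modelling:

1. **Change ratios** — per country and crop,
   `rH = H_2015 / H_2010` and `rP = P_2015 / P_2010` from three-year window
   means (2009–2011, 2014–2016), with a no-change default of 1.0 for zero or
   unreported statistics; ~160 FAOSTAT crops are aggregated to the 26 GAEZ
   crop categories by 2015-harvested-area weights. Fodder crops (no longer
   reported by FAOSTAT) follow national cattle + buffalo herd changes.
   Special registries handle a mid-period country split (Sudan-like), 49
   no-data islands/regions, and 9 disputed areas (all frozen at 1.0).
2. **Grid update** — each cell is scaled by the fraction-weighted mean
   ratio of the countries sharing it
   (`sum_i f_i r_i / sum_i f_i`), capped so that total cropland never
   exceeds 99% of the cell area; yields are `Y = P / H` with `Y = 0` where
   `H = 0`.
3. **Monthly disaggregation** — annual harvested area is spread over
   MIRCA2000-style subcrop calendars,
   `A_G = sum_n (A_Mn / H_M) * H_G`, borrowing the calendar from the
   great-circle-nearest cell where a cell lacks one; each cell-month is
   truncated to 99% of cell area by a removal-order priority (rainfed
   first, staples last).
4. **Validation tools** — zonal sums, OLS comparison statistics
   (r², slope, RMSE), cropland extent bounds (min/max re-use assumptions)
   and harvested-area reconciliation reports.
5. **Synthetic worlds** — seeded miniature inputs with exact ground truth,
   so every rule above is testable to numerical precision.

Tables in and out are tibbles; raster layers are a light `crop_grid`
matrix class with GeoTIFF/NetCDF I/O following the published naming
templates and no-data sentinels.

## Worked example

```r
library(gaezplus)
library(dplyr)

# a seeded miniature world: 3 countries + a splitting country, islands,
# disputed area, split cells, 6 crops, subcrop calendars
w <- generate_world(world_config(seed = 7))

ratios <- build_ratio_table(w$stats, w$livestock,
                            registry = w$registry, splits = w$splits,
                            countries = unique(w$fractions$adm0_code))
ratios |> filter(adm0_code == 1001, gaez_crop %in% c("Wheat", "Rice"))
#> # A tibble: 2 x 4
#>   adm0_code gaez_crop    rH    rP
#>       <int> <chr>     <dbl> <dbl>
#> 1      1001 Rice      0.724 0.913
#> 2      1001 Wheat     1.24  1.20

ann <- run_annual_update(w, ratios = ratios)
rc  <- recovery_check(ann, w$truth)
max(rc$rel_error, na.rm = TRUE)
#> [1] 3.27299e-16          # country totals hit their targets exactly

mo <- run_monthly(ann$H, w$calendar)
mo$removal$max_removed
#> [1] 0                    # nothing truncated in this uncapped world

# write the annual layer set (26-crop worlds give the canonical 156 files)
files <- write_annual_layers(ann, tempfile())
nrow(files)
#> [1] 36                   # 6 crops x 3 variables x 2 managements
```

The ratios printed above are the world's true multipliers recovered from
the generated statistics; `recovery_check()` confirms that per-country
2015 totals equal 2010 totals times the ratio to machine precision when the
99% cap never binds, and `run_monthly()` reports how much area the monthly
cap removed (zero here).

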