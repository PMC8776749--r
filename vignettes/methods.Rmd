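---
title: "Updating gridded crop statistics with country-level ratios: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Updating gridded crop statistics with country-level ratios: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Global gridded crop datasets (harvested area, production, yield per crop and
production system at 5-arcminute resolution) are expensive to rebuild, so
they lag the present by many years. A practical way to refresh them is to
keep the sub-national spatial pattern of an existing gridded base year and
move every cell with the *national* change observed in country statistics.
`gaezplus` implements that pipeline: circa-2010 gridded crop layers are
updated to 2015 with FAOSTAT-style country ratios, yields are derived, and
the annual harvested areas are disaggregated into monthly physical cropland
area using MIRCA2000-style crop calendars with up to five subcrops per crop.

The package is organised tidyverse-style: tabular objects (statistics,
concordances, ratio tables, calendars, reports) are tibbles flowing through
dplyr verbs, while raster layers are a light matrix-backed `crop_grid`
class with lon/lat georeferencing (a raster is not naturally a data frame,
and the canonical 2160 x 4320 global layer would be wasteful in long form).

## The model

### National change ratios

For each country and each FAOSTAT crop $c$, harvested area $H$ and
production $P$ are averaged over three-year windows (2009-2011 representing
2010, 2014-2016 representing 2015), and ratios are formed:

$$rH_c = H_{2015}/H_{2010}, \qquad rP_c = P_{2015}/P_{2010}.$$

If either window value is zero or unreported, both ratios default to 1.0
(no change). Missing years *inside* a window are dropped from the mean
rather than failing, which is the stated purpose of the averaging; a window
with no data at all is "unreported". The roughly 160 FAOSTAT crops are then
aggregated to the 26 GAEZ crop categories by an average weighted by
FAOSTAT year-2015 harvested area. The same harvested-area weights are used
for both $rH$ and $rP$; where the literal year-2015 value is missing we
fall back to the 2014-2016 window mean, then to zero. All member weights
zero falls back to the no-change default of 1.0.

Fodder crops are no longer reported by FAOSTAT at all, so their change
ratio is taken from the change in national cattle plus buffalo herd sizes
(head counts summed across species before the ratio, since the two herds
jointly proxy fodder demand). The same livestock ratio is applied to both
the harvested-area and the production layers of the fodder category, since
no independent production signal exists.

Three special registries override the statistics: a country that split
during the period (Sudan / South Sudan) has its pre-split years apportioned
to the successors by their per-crop shares in 2012, the first year both
reported (50/50 when both report zero); 49 small regions and islands with
no FAOSTAT data, and 9 disputed areas, are frozen at ratio 1.0.

### Applying ratios to cells

Grid cells can straddle countries. With $f_i^k$ the fraction of cell $k$ in
unit $i$, the update is

$$H^k_{2015} = H^k_{2010} \cdot \frac{\sum_i f_i^k\, rH_{c,i}}{\sum_i f_i^k}.$$

The denominator is a deliberate design choice: the unnormalised sum
conflates *land fraction* with *ratio weighting*, so a coastal cell lying
80% in one country would receive 0.8 times that country's ratio and the
no-change identity (all ratios 1) would not hold. Normalising by
$\sum_i f_i^k$ gives each cell the fraction-weighted mean ratio of the
units that share it, and preserves both the identity and exact per-country
conservation for cells wholly inside one unit.

After the update, if the combined harvested area of all crops and both
managements in a cell exceeds 99% of the cell area, all crop areas in the
cell are scaled down proportionally to fit. Proportional scaling preserves
the crop mix; the alternative reading of "reduced equally" (equal absolute
subtraction) can drive small crops negative and was rejected. The cap
applies to the harvested-area layers only; production is left unchanged,
so capped cells show correspondingly higher yields. Cell areas come from an
authalic sphere ($R = 6{,}371{,}007.2$ m,
$A = R^2\,\Delta\lambda\,(\sin\varphi_N - \sin\varphi_S)$), which is
symmetric, monotone toward the poles, and amply accurate for a 1% headroom
rule.

Yields are $Y = P/H$ (t/ha, since both layers are in thousands), with
$Y = 0$ wherever $H = 0$.

### Monthly disaggregation

Each GAEZ crop is matched to one or two MIRCA2000 crops (18 of 26 match
1:1). For a cell with annual harvested area $H_G$ and a calendar whose
subcrops $n$ have physical areas $A_{M,n}$ summing to $H_M$, each subcrop
carries

$$A_{G,n} = \frac{A_{M,n}}{H_M} H_G$$

in each month of its growing season (seasons may wrap across December,
occupying $\{start..12\} \cup \{1..end\}$). A subcrop's area is constant
over its growing months, and the subcrop areas sum back to $H_G$ exactly -
the invariant the test suite checks to 1e-9. Multi-match categories pool
the subcrop lists of both MIRCA crops and use their summed area as $H_M$,
preserving both seasonal patterns.

A cell can have crop area but no calendar (the crop expanded after the
calendar era). The calendar is then borrowed from the nearest cell, by
great-circle distance between cell centers, that has the matching MIRCA
crop with positive area *in the same management*; ties break by row then
column. Distance metric and tie-breaking are our own choices - the
originating method does not state them - made for determinism; the package
cross-checks the lookup against an exhaustive independent scan.

Monthly totals are then capped per cell-month at 99% of the cell area
(at least 1% of land is retained for infrastructure and other cover).
Removal is ordered: all rainfed crops in ascending removal order (1 =
removed first; staples like wheat at 21 are removed last), then irrigated
crops in the same order, zeroing each crop in turn and partially reducing
the last one touched. Several crops share orders 1-3; ties break
alphabetically by category name for determinism. Removal is resolved at
crop level: all subcrops of a crop are scaled by the crop's post-removal
fraction. Because each month is capped independently - exactly as the
procedure states - truncation can break a subcrop's constancy across
months; we accept that as faithful rather than re-smoothing.

Crop/management layers that are entirely zero (irrigated cassava in the
canonical product) emit no monthly cubes.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `cap_fraction` | 0.99 | share of cell area cropland may occupy (annual and monthly caps) |
| window centre years | 2010, 2015 | three-year statistic windows (fixed by the product definition) |
| sphere radius | 6,371,007.2 m | authalic radius for cell areas |
| no-data sentinels | -3.39999999999999996e+38 (GeoTIFF), -3.4e+38 (NetCDF) | published values, preserved bit-for-bit in files |

## The synthetic worlds

`generate_world()` builds miniature inputs with the full structure the
pipeline assumes: a 36 x 72 grid of 5-degree cells (the same code paths as
5-arcminute cells, at seconds-scale cost), 3 regular countries plus a
splitting country, split border cells, partial-land coastal cells, a
no-data island and a disputed area taken from the canonical registry,
statistics with missing years, livestock series, and one-to-three-subcrop
calendars including a wrap season and a two-season rice.

Two constructions make recovery *exact* rather than approximate, so tests
can assert to 1e-6 instead of eyeballing:

* every year inside a statistics window carries the country's gridded 2010
  sum (times the true multiplier for the 2015 window), so missing-year
  noise never moves the window mean;
* crop area is placed only in cells wholly inside one administrative unit;
  split border cells carry zero crop area. Mixed-ratio cells are exercised
  by unit tests of `apply_ratios()` directly, because a cell shared between
  countries with different ratios genuinely cannot conserve both countries'
  totals at once - a property of the method, not a bug.

Consequently the generator emulates the *statistical* structure of the real
inputs, not their geography: passing tests demonstrate that the machinery
is exact under the stated rules, not that any particular real-world number
is reproduced. The headline totals of the published 2015 product require
the real circa-2010 rasters, FAOSTAT archives, GAUL cell fractions and
MIRCA2000 calendars, which are external downloads outside this package's
scope.

All randomness flows through a single integer seed; the same seed yields a
byte-identical bundle.

## Numerical choices and degenerate inputs

* Ratios, weights and caps are computed in double precision; files are
  written float32 to honour the published no-data sentinels.
* Zero/missing statistics give ratio 1.0; all-zero aggregation weights give
  1.0; a unit present in the cell-fraction table but absent from statistics
  and registry gets 1.0 with a warning.
* A cell-month exactly at the 99% boundary is left untouched (strict
  inequality triggers the cap).
* `scale_subcrops()` refuses an empty or zero-area calendar ("no
  calendar"): callers must resolve a donor cell first, which keeps the
  fallback an explicit, logged step.
* The GeoTIFF writer produces uncompressed striped float32 with standard
  georeferencing tags; files were verified to parse in an independent TIFF
  implementation. NetCDF cubes use deflate level 7, matching the published
  format.

## Problem sizes

The test suite and the acceptance script run entirely on generated worlds:
the default 36 x 72 grid with 6 crops, a 26-crop world for the file
inventory and monthly runs, and 1,000 random truncation instances for the
removal-order oracle. These sizes were chosen so the whole suite completes
in a few minutes while still exercising every rule, including the caps,
splits, donors and wrap seasons.

## Known limitations

* Calendars are frozen at the MIRCA2000 era; no post-2000 changes in crop
  rotations or planting dates are represented.
* The irrigated/rainfed partition of the base year is carried forward
  unchanged; the ratios move both managements together within a country.
* A crop reported in the 2015 statistics but absent from a country's 2010
  grid cells acquires no new cells: the update inherits the base-year
  spatial support by construction.
* Cell-level values should be interpreted with care; the method is designed
  to be right in aggregate (country, basin), which is what the zonal
  validation tools measure.
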