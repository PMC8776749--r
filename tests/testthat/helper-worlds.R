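# Worlds are expensive enough to share across test files; built once per run.
.world_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (is.null(.world_cache[[key]])) .world_cache[[key]] <- maker()
  .world_cache[[key]]
}

ratios_for <- function(w) {
  build_ratio_table(w$stats, w$livestock, concordance = w$concordance,
                    registry = w$registry, splits = w$splits,
                    countries = unique(w$fractions$adm0_code))
}

default_world <- function() cached("default", function() {
  w <- generate_world(world_config(seed = 101))
  w$ratios <- ratios_for(w)
  w
})

default_annual <- function() cached("default_annual", function() {
  run_annual_update(default_world())
})

default_monthly <- function() cached("default_monthly", function() {
  w <- default_world()
  run_monthly(default_annual()$H, w$calendar, w$matches)
})

stress_world <- function() cached("stress", function() {
  w <- generate_world(world_config(seed = 202, cap_stress = TRUE))
  w$ratios <- ratios_for(w)
  w
})

stress_annual <- function() cached("stress_annual", function() {
  run_annual_update(stress_world())
})

# after the annual cap no cell-month can exceed 99% of the cell area
# (monthly physical area never exceeds annual harvested area), so the
# monthly cap is exercised on layers updated without the annual cap
stress_monthly <- function() cached("stress_monthly", function() {
  w <- stress_world()
  uncapped <- run_annual_update(w, cap_fraction = Inf)
  run_monthly(uncapped$H, w$calendar, w$matches)
})

identity_world <- function() cached("identity", function() {
  w <- generate_world(world_config(seed = 303, multipliers = 1))
  w$ratios <- ratios_for(w)
  w
})

# a tiny hand-built grid for unit tests
tiny_grid <- function(values, cellsize = 5) {
  crop_grid(values, west = -180, north = 90, cellsize = cellsize)
}
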