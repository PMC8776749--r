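#' Configuration for a synthetic miniature world
#'
#' Synthetic worlds reproduce the statistical structure the pipeline
#' assumes on a grid small enough for seconds-scale tests: a handful of
#' rectangular countries on a land band, split border cells, partial-land
#' coastal cells, a country that splits into two successors mid-period
#' ("Sudan-like"), a no-data island and a disputed area drawn from the
#' canonical special-region registry, per-country crop statistics whose
#' window means are exactly consistent with the gridded 2010 layers, and
#' per-cell subcrop calendars. Noise is realised as missing years in the
#' statistics (never value jitter), exercising the three-year-mean rule
#' without breaking exact recovery.
#'
#' @param seed Integer seed; the same seed yields an identical bundle.
#' @param rows,cols Grid shape (default 36 x 72: 5-degree cells run through
#'   the same code paths as 5-arcminute ones).
#' @param n_countries Number of regular countries (codes 1001, 1002, ...).
#' @param crops GAEZ category subset, or `"all"` for the full 26.
#' @param multipliers Optional tibble `adm0_code`, `gaez_crop`, `rH`, `rP`
#'   of true change multipliers, or a single number applied everywhere
#'   (e.g. 1 for an identity world); drawn log-uniform in about [0.67, 1.5]
#'   when omitted.
#' @param sudan_split,no_data_island,disputed_area,wrap_season,multi_subcrop,cap_stress
#'   Feature flags.
#' @param orphan_calendar_cells Number of occupied cells per (crop,
#'   management) whose calendar is withheld, forcing the nearest-cell
#'   fallback.
#' @return A `world_config` list.
#' @export
world_config <- function(seed = 1L, rows = 36L, cols = 72L, n_countries = 3L,
                         crops = c("Wheat", "Rice", "Maize", "Other_cereals",
                                   "Vegetables", "Fodder_crop"),
                         multipliers = NULL,
                         sudan_split = TRUE, no_data_island = TRUE,
                         disputed_area = TRUE, wrap_season = TRUE,
                         multi_subcrop = TRUE, cap_stress = FALSE,
                         orphan_calendar_cells = 1L) {
  if (identical(crops, "all")) crops <- gaez_crop_names()
  stopifnot(all(crops %in% gaez_crop_names()), n_countries >= 1L)
  structure(list(seed = as.integer(seed), rows = as.integer(rows),
                 cols = as.integer(cols), n_countries = as.integer(n_countries),
                 crops = crops, multipliers = multipliers,
                 sudan_split = sudan_split, no_data_island = no_data_island,
                 disputed_area = disputed_area, wrap_season = wrap_season,
                 multi_subcrop = multi_subcrop, cap_stress = cap_stress,
                 orphan_calendar_cells = as.integer(orphan_calendar_cells)),
            class = "world_config")
}

# Deterministic rectangular layout: regular countries side by side on a land
# band, successors of the split country stacked in the last block, island
# and disputed area outside/inside the band. Returns the cell-fraction
# table, country codes by role, and the land mask.
world_layout <- function(config) {
  rows <- config$rows; cols <- config$cols
  band_rows <- seq(max(4L, round(rows * 0.25)), min(rows - 4L, round(rows * 0.72)))
  n_blocks <- config$n_countries + (if (config$sudan_split) 1L else 0L)
  block_cols <- max(4L, floor((cols - 8L) / n_blocks))
  regular <- 1000L + seq_len(config$n_countries)

  fr <- list()
  add <- function(rws, cls, code, fraction = 1) {
    fr[[length(fr) + 1L]] <<- tidyr::expand_grid(cell_row = rws,
                                                 cell_col = cls) |>
      dplyr::mutate(adm0_code = code, fraction = fraction)
  }
  for (i in seq_len(config$n_countries)) {
    c0 <- 4L + (i - 1L) * block_cols + 1L
    c1 <- 4L + i * block_cols
    # interior; coastal top row has partial land (fraction sums < 1)
    add(band_rows[-1], c0:(c1 - 1L), regular[i])
    add(band_rows[1], c0:(c1 - 1L), regular[i], fraction = 0.8)
    # border column shared with the next block
    if (i < n_blocks) {
      add(band_rows, c1, regular[i], fraction = 0.55)
      nxt <- if (i < config$n_countries) regular[i + 1L] else 2001L
      add(band_rows, c1, nxt, fraction = 0.45)
    } else {
      add(band_rows, c1, regular[i])
    }
  }
  split_children <- integer(0)
  if (config$sudan_split) {
    c0 <- 4L + config$n_countries * block_cols + 1L
    c1 <- 4L + (config$n_countries + 1L) * block_cols
    half <- band_rows[seq_len(ceiling(length(band_rows) / 2))]
    add(half, c0:c1, 2001L)
    add(setdiff(band_rows, half), c0:c1, 2002L)
    split_children <- c(2001L, 2002L)
  }
  island <- integer(0)
  if (config$no_data_island) {
    island <- 98L  # registry code of a no-data region
    add(rows - 2L, c(3L, 4L), island)
  }
  disputed <- integer(0)
  if (config$disputed_area) {
    disputed <- 102L  # registry code of a disputed area
    add(band_rows[2:3], c(3L, 4L), disputed)
  }
  fractions <- dplyr::bind_rows(fr) |>
    dplyr::arrange(.data$cell_row, .data$cell_col, .data$adm0_code)
  bad <- fractions |>
    dplyr::group_by(.data$cell_row, .data$cell_col) |>
    dplyr::summarise(s = sum(.data$fraction), .groups = "drop") |>
    dplyr::filter(.data$s > 1 + 1e-9)
  stopifnot(nrow(bad) == 0L)
  list(fractions = fractions, regular = regular,
       split_children = split_children, split_parent = 2000L,
       island = island, disputed = disputed)
}

#' Generate a synthetic world with ground truth
#'
#' Emits the full input bundle of the pipeline - 2010 gridded harvested
#' area and production per crop and management, a FAOSTAT-style statistics
#' table, livestock series, the cell-fraction table, subcrop calendars and
#' the special-region registry - together with ground truth (the true
#' change-ratio table, expected 2015 country totals, and the donor-cell map
#' for calendar-less cells) derived from the configuration alone.
#'
#' The statistics are constructed to be exactly consistent with the 2010
#' grids: every year inside a three-year window carries the country's
#' gridded sum (times the true multiplier for the 2015 window), so ratio
#' recovery is exact by construction and missing years do not perturb it.
#'
#' @param config A [world_config()].
#' @return A list (`world_bundle`): `grids` are under `h2010`/`p2010` as
#'   `[[crop]][[management]]`, plus `fractions`, `stats`, `livestock`,
#'   `calendar`, `registry`, `splits`, `concordance`, `matches`, `geo`,
#'   `config` and `truth`.
#' @export
generate_world <- function(config = world_config()) {
  withr::with_seed(config$seed, generate_world_impl(config))
}

generate_world_impl <- function(config) {
  rows <- config$rows; cols <- config$cols
  cellsize <- 180 / rows
  stopifnot(isTRUE(all.equal(cols * cellsize, 360)))
  layout <- world_layout(config)
  fractions <- layout$fractions
  concordance <- read_crop_concordance()
  matches <- read_mirca_matches()
  registry <- read_special_regions() |>
    dplyr::filter(.data$adm0_code %in% c(layout$island, layout$disputed))

  land <- fractions |> dplyr::distinct(.data$cell_row, .data$cell_col)
  base <- matrix(NA_real_, rows, cols)
  base[cbind(land$cell_row, land$cell_col)] <- 0
  geo <- crop_grid(base, west = -180, north = 90, cellsize = cellsize)

  # cells wholly inside one unit carry the crop area; split border cells and
  # multi-unit cells stay empty so per-country totals are exactly
  # conserved under the ratio update
  cell_units <- fractions |>
    dplyr::group_by(.data$cell_row, .data$cell_col) |>
    dplyr::summarise(n_units = dplyr::n(),
                     adm0_code = .data$adm0_code[1], .groups = "drop")
  sole <- cell_units |> dplyr::filter(.data$n_units == 1L)

  all_units <- sort(unique(fractions$adm0_code))
  truth_units <- setdiff(all_units, layout$split_parent)

  # true multipliers: regular countries and split children vary, special
  # regions are fixed at 1
  mult <- config$multipliers
  if (is.numeric(mult) && length(mult) == 1L) {
    const <- as.numeric(mult)
    mult <- tidyr::expand_grid(adm0_code = truth_units,
                               gaez_crop = config$crops) |>
      dplyr::mutate(rH = const, rP = const)
  }
  if (is.null(mult)) {
    varying <- c(layout$regular, layout$split_children)
    mult <- tidyr::expand_grid(adm0_code = truth_units,
                               gaez_crop = config$crops) |>
      dplyr::mutate(
        rH = ifelse(.data$adm0_code %in% varying,
                    exp(stats::runif(dplyr::n(), -0.4, 0.4)), 1),
        rP = ifelse(.data$adm0_code %in% varying,
                    exp(stats::runif(dplyr::n(), -0.4, 0.4)), 1)
      ) |>
      # the livestock-driven fodder update moves area and production alike
      dplyr::mutate(rP = ifelse(.data$gaez_crop == "Fodder_crop",
                                .data$rH, .data$rP))
  }

  # scatter log-normal 2010 areas over each unit's sole cells
  mgmts <- c("Irrigated", "Rainfed")
  h2010 <- list(); p2010 <- list()
  for (cr in config$crops) {
    h2010[[cr]] <- list(); p2010[[cr]] <- list()
    for (m in mgmts) {
      hm <- base; pm <- base
      for (u in truth_units) {
        cells <- sole |> dplyr::filter(.data$adm0_code == u)
        if (nrow(cells) == 0L) next
        occ <- stats::runif(nrow(cells)) < 0.7
        if (!any(occ)) occ[1] <- TRUE
        n_occ <- sum(occ)
        h <- stats::rlnorm(n_occ, meanlog = log(80), sdlog = 0.5)
        y <- stats::runif(n_occ, 1.5, 8)  # t/ha
        idx <- cbind(cells$cell_row[occ], cells$cell_col[occ])
        hm[idx] <- hm[idx] + h
        pm[idx] <- pm[idx] + h * y
      }
      h2010[[cr]][[m]] <- crop_grid(hm, -180, 90, cellsize)
      p2010[[cr]][[m]] <- crop_grid(pm, -180, 90, cellsize)
    }
  }
  # irrigated-cassava-like empty layer: zero out irrigated Cassava
  if ("Cassava" %in% config$crops) {
    z <- h2010[["Cassava"]][["Irrigated"]]$values
    z[!is.na(z)] <- 0
    h2010[["Cassava"]][["Irrigated"]]$values <- z
    p2010[["Cassava"]][["Irrigated"]]$values <- z
  }
  if (config$cap_stress) {
    # inflate one cell of the first regular country past the 99% cap
    cell <- sole |>
      dplyr::filter(.data$adm0_code == layout$regular[1]) |>
      dplyr::slice(1)
    ca <- cell_area(cell$cell_row, geo)
    # 2.5x the cap so that even single-month crop overlaps overflow
    per_layer <- 2.5 * 0.99 * ca / (length(config$crops) * 2)
    for (cr in config$crops) for (m in mgmts) {
      if (cr == "Cassava" && m == "Irrigated") next
      h2010[[cr]][[m]]$values[cell$cell_row, cell$cell_col] <- per_layer
      p2010[[cr]][[m]]$values[cell$cell_row, cell$cell_col] <- per_layer * 3
    }
  }

  world_stats <- synth_statistics(config, layout, h2010, p2010, mult,
                                  concordance)
  calendar <- synth_calendar(config, layout, h2010, matches)
  truth <- synth_truth(config, layout, h2010, mult, fractions, calendar,
                       matches, geo)

  splits <- if (config$sudan_split) {
    tibble::tibble(parent = layout$split_parent,
                   child1 = layout$split_children[1],
                   child2 = layout$split_children[2])
  } else NULL

  list(h2010 = h2010, p2010 = p2010, fractions = fractions,
       stats = world_stats$stats, livestock = world_stats$livestock,
       calendar = calendar, registry = registry, splits = splits,
       concordance = concordance, matches = matches, geo = geo,
       config = config, truth = truth,
       ratios = NULL)
}

# Country statistics exactly consistent with the gridded 2010 sums; the
# 2015-window values carry the true multipliers. Fodder areas are gridded
# but never reported (livestock drives them); special regions report
# nothing.
synth_statistics <- function(config, layout, h2010, p2010, mult,
                             concordance) {
  report_units <- c(layout$regular, layout$split_children)
  rows <- list()
  lv_rows <- list()
  unit_sum <- function(grids, cr, u) {
    s <- 0
    for (m in names(grids[[cr]])) {
      v <- grids[[cr]][[m]]$values
      cells <- layout$fractions |> dplyr::filter(.data$adm0_code == u)
      s <- s + sum(v[cbind(cells$cell_row, cells$cell_col)] * cells$fraction,
                   na.rm = TRUE)
    }
    s
  }
  for (u in report_units) {
    is_child <- u %in% layout$split_children
    for (cr in config$crops) {
      if (cr == "Fodder_crop") next  # no longer reported by FAOSTAT
      members <- concordance$faostat_code[concordance$gaez_crop == cr]
      members <- members[seq_len(min(2L, length(members)))]
      share <- if (length(members) == 2L) c(0.6, 0.4) else 1
      rH <- mult$rH[mult$adm0_code == u & mult$gaez_crop == cr]
      rP <- mult$rP[mult$adm0_code == u & mult$gaez_crop == cr]
      sH <- unit_sum(h2010, cr, u) * 1000  # 1000 ha -> ha
      sP <- unit_sum(p2010, cr, u) * 1000  # 1000 t -> t
      y10 <- if (is_child) 2010L else 2009:2011
      drop <- if (!is_child && stats::runif(1) < 0.4) sample(c(2009L, 2011L), 1L) else NA
      y10 <- setdiff(y10, drop)
      y15 <- 2014:2016
      y12 <- if (is_child) 2012L else integer(0)
      for (k in seq_along(members)) {
        mk_rows <- function(years, element, val) {
          if (length(years) == 0L || val < 0) return(NULL)
          tibble::tibble(area_code = u, item_code = members[k],
                         element = element, year = years, value = val)
        }
        rows[[length(rows) + 1L]] <- dplyr::bind_rows(
          mk_rows(y10, "area_harvested", sH * share[k]),
          mk_rows(y15, "area_harvested", sH * share[k] * rH),
          mk_rows(y12, "area_harvested", sH * share[k] * 1.1),
          mk_rows(y10, "production", sP * share[k]),
          mk_rows(y15, "production", sP * share[k] * rP),
          mk_rows(y12, "production", sP * share[k] * 1.1)
        )
      }
    }
    # livestock: cattle + buffalo herd change drives the fodder ratio
    if ("Fodder_crop" %in% config$crops) {
      rF <- mult$rH[mult$adm0_code == u & mult$gaez_crop == "Fodder_crop"]
      heads <- round(stats::runif(1, 2e5, 2e6))
      lv_rows[[length(lv_rows) + 1L]] <- dplyr::bind_rows(
        tidyr::expand_grid(species = c("cattle", "buffalo"), year = 2009:2011) |>
          dplyr::mutate(area_code = u, value = heads),
        tidyr::expand_grid(species = c("cattle", "buffalo"), year = 2014:2016) |>
          dplyr::mutate(area_code = u, value = heads * rF)
      )
    }
  }
  # pre-split parent: reports only pre-split years, summed over children
  if (config$sudan_split) {
    kids <- layout$split_children
    child_rows <- dplyr::bind_rows(rows) |>
      dplyr::filter(.data$area_code %in% kids, .data$year == 2010L)
    parent <- child_rows |>
      dplyr::group_by(.data$item_code, .data$element) |>
      dplyr::summarise(value = sum(.data$value), .groups = "drop") |>
      tidyr::expand_grid(year = 2009:2010) |>
      dplyr::mutate(area_code = layout$split_parent)
    # children report from 2012 on: drop their synthetic 2010 rows
    rows <- list(
      dplyr::bind_rows(rows) |>
        dplyr::filter(!(.data$area_code %in% kids & .data$year < 2012L)),
      parent
    )
  }
  stats <- dplyr::bind_rows(rows) |>
    dplyr::select("area_code", "item_code", "element", "year", "value") |>
    dplyr::arrange(.data$area_code, .data$item_code, .data$element, .data$year)
  livestock <- if (length(lv_rows)) {
    dplyr::bind_rows(lv_rows) |>
      dplyr::select("area_code", "species", "year", "value")
  } else NULL
  list(stats = stats, livestock = livestock)
}

# Subcrop calendars, generated per MIRCA crop class (as MIRCA does): a
# class shared by several GAEZ categories (Others_annual feeds Stimulants,
# Tobacco, Vegetables, ...) has one set of entries per cell, and a class
# never exceeds 2 subcrops, so pooling two classes stays within the 5-
# subcrop limit. A few occupied cells per class are withheld to exercise
# the nearest-cell fallback.
synth_calendar <- function(config, layout, h2010, matches) {
  class_crops <- list()
  for (cr in config$crops) {
    for (mc in lookup_mirca_match(cr, matches)$mirca_crops[[1]]) {
      class_crops[[mc]] <- union(class_crops[[mc]], cr)
    }
  }
  d <- dim(h2010[[1]][[1]]$values)
  rows <- list()
  for (mc in sort(names(class_crops))) {
    seasons <- season_plan(mc, config)
    for (m in c("Irrigated", "Rainfed")) {
      occ_mask <- matrix(FALSE, d[1], d[2])
      for (cr in class_crops[[mc]]) {
        v <- h2010[[cr]][[m]]$values
        occ_mask <- occ_mask | (!is.na(v) & v > 0)
      }
      occ <- which(occ_mask, arr.ind = TRUE)
      dimnames(occ) <- NULL
      if (nrow(occ) == 0L) next
      n_orphan <- min(config$orphan_calendar_cells, nrow(occ) - 1L)
      keep <- setdiff(seq_len(nrow(occ)),
                      if (n_orphan > 0L) seq_len(n_orphan) else integer(0))
      for (j in keep) {
        area_draws <- stats::rlnorm(nrow(seasons), log(40), 0.4)
        for (s in seq_len(nrow(seasons))) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            cell_row = occ[j, 1], cell_col = occ[j, 2], mirca_crop = mc,
            management = m, subcrop = seasons$subcrop[s],
            start_month = seasons$start[s], end_month = seasons$end[s],
            area = area_draws[s] * seasons$weight[s])
        }
      }
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$mirca_crop, .data$management, .data$cell_row,
                   .data$cell_col, .data$subcrop)
}

# Season templates per MIRCA class: two-season rice, a wrap-season wheat,
# single offset seasons elsewhere; deterministic given the class name.
season_plan <- function(mc, config) {
  if (config$multi_subcrop && mc == "Rice") {
    tibble::tibble(subcrop = 1:2, start = c(1L, 6L), end = c(5L, 10L),
                   weight = c(0.6, 0.4))
  } else if (config$wrap_season && mc == "Wheat") {
    tibble::tibble(subcrop = 1L, start = 11L, end = 3L, weight = 1)
  } else {
    offset <- sum(utf8ToInt(mc)) %% 6L
    tibble::tibble(subcrop = 1L, start = 3L + offset, end = 7L + offset,
                   weight = 1)
  }
}

# Ground truth derivable without running the pipeline: the expected ratio
# table, expected 2015 totals per unit/crop/management, and the donor map
# for calendar-less cells (independent spherical-law-of-cosines scan).
synth_truth <- function(config, layout, h2010, mult, fractions, calendar,
                        matches, geo) {
  ratio_truth <- mult |>
    dplyr::mutate(
      rH = ifelse(.data$adm0_code %in% c(layout$island, layout$disputed),
                  1, .data$rH),
      rP = ifelse(.data$adm0_code %in% c(layout$island, layout$disputed),
                  1, .data$rP)
    )
  totals <- list()
  for (cr in config$crops) {
    for (m in names(h2010[[cr]])) {
      v <- h2010[[cr]][[m]]$values
      t0 <- fractions |>
        dplyr::mutate(h = v[cbind(.data$cell_row, .data$cell_col)] *
                        .data$fraction) |>
        dplyr::group_by(.data$adm0_code) |>
        dplyr::summarise(h2010 = sum(.data$h, na.rm = TRUE), .groups = "drop")
      totals[[length(totals) + 1L]] <- t0 |>
        dplyr::left_join(ratio_truth |> dplyr::filter(.data$gaez_crop == cr),
                         by = "adm0_code") |>
        dplyr::mutate(gaez_crop = cr, management = m,
                      rH = dplyr::coalesce(.data$rH, 1),
                      expected_h2015 = .data$h2010 * .data$rH) |>
        dplyr::select("adm0_code", "gaez_crop", "management", "h2010",
                      "expected_h2015")
    }
  }
  donor_map <- truth_donor_map(config, h2010, calendar, matches, geo)
  list(ratios = ratio_truth, totals = dplyr::bind_rows(totals),
       donors = donor_map)
}

# Independent nearest-donor scan (spherical law of cosines, plain loops).
truth_donor_map <- function(config, h2010, calendar, matches, geo) {
  sloc <- function(lat1, lon1, lat2, lon2) {
    r <- pi / 180
    d <- sin(lat1 * r) * sin(lat2 * r) +
      cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
    acos(pmin(1, pmax(-1, d)))
  }
  rows <- list()
  for (cr in config$crops) {
    mirca <- lookup_mirca_match(cr, matches)$mirca_crops[[1]]
    for (m in c("Irrigated", "Rainfed")) {
      v <- h2010[[cr]][[m]]$values
      occ <- which(!is.na(v) & v > 0, arr.ind = TRUE)
      dimnames(occ) <- NULL
      cal <- calendar |>
        dplyr::filter(.data$mirca_crop %in% mirca, .data$management == m,
                      .data$area > 0) |>
        dplyr::distinct(.data$cell_row, .data$cell_col)
      if (nrow(occ) == 0L || nrow(cal) == 0L) next
      has_cal <- paste(occ[, 1], occ[, 2]) %in% paste(cal$cell_row,
                                                      cal$cell_col)
      for (j in which(!has_cal)) {
        lat0 <- cell_center_lat(occ[j, 1], geo)
        lon0 <- cell_center_lon(occ[j, 2], geo)
        best <- NULL
        for (k in seq_len(nrow(cal))) {
          dk <- sloc(lat0, lon0, cell_center_lat(cal$cell_row[k], geo),
                     cell_center_lon(cal$cell_col[k], geo))
          cand <- c(dk, cal$cell_row[k], cal$cell_col[k])
          if (is.null(best) || cand[1] < best[1] - 1e-12 ||
              (abs(cand[1] - best[1]) <= 1e-12 &&
                 (cand[2] < best[2] ||
                    (cand[2] == best[2] && cand[3] < best[3])))) {
            best <- cand
          }
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gaez_crop = cr, management = m,
          cell_row = occ[j, 1], cell_col = occ[j, 2],
          donor_row = best[2], donor_col = best[3])
      }
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble()
}

#' Check pipeline outputs against the world's ground truth
#'
#' Compares achieved per-country per-crop 2015 harvested-area totals
#' (restricted through the cell fractions) with the expected totals derived
#' from the configuration, and flags relative errors above the tolerance.
#'
#' @param annual Output of [run_annual_update()].
#' @param truth A `truth` element of [generate_world()] output.
#' @param tolerance Relative-error threshold, default 1e-6.
#' @return A tibble with `expected_h2015`, `achieved`, `rel_error`, `flag`.
#' @export
recovery_check <- function(annual, truth, tolerance = 1e-6) {
  annual$conservation |>
    dplyr::select("adm0_code", "gaez_crop", "management", "achieved") |>
    dplyr::left_join(truth$totals,
                     by = c("adm0_code", "gaez_crop", "management")) |>
    dplyr::mutate(
      rel_error = ifelse(.data$expected_h2015 > 0,
                         abs(.data$achieved - .data$expected_h2015) /
                           .data$expected_h2015,
                         abs(.data$achieved - .data$expected_h2015)),
      flag = .data$rel_error > tolerance
    )
}
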