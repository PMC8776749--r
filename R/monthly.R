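#' Months covered by a growing season
#'
#' Seasons may wrap across December: planting month 11 with harvest month 2
#' occupies months 11, 12, 1, 2.
#'
#' @param start_month,end_month Integers in 1..12.
#' @return Integer vector of months.
#' @export
season_months <- function(start_month, end_month) {
  stopifnot(start_month %in% 1:12, end_month %in% 1:12)
  if (start_month <= end_month) start_month:end_month
  else c(start_month:12L, 1:end_month)
}

#' Annual harvested area implied by a MIRCA-style calendar
#'
#' The calendar-implied annual harvested area of a crop in a cell is the sum
#' of its subcrop physical areas (each subcrop is one harvest per year), 0 if
#' the crop is absent.
#'
#' @param calendar Calendar tibble: `cell_row`, `cell_col`, `mirca_crop`,
#'   `management`, `subcrop`, `start_month`, `end_month`, `area` (1000 ha,
#'   constant over the subcrop's growing months).
#' @param cell_row,cell_col Cell index.
#' @param mirca_crops Character vector of MIRCA crop names (1-2; multi-match
#'   GAEZ categories pool their MIRCA crops).
#' @param management `"Irrigated"` or `"Rainfed"`.
#' @return Annual harvested area in 1000 ha.
#' @export
mirca_annual_harvested_area <- function(calendar, cell_row, cell_col,
                                        mirca_crops, management) {
  sel <- calendar$cell_row == cell_row & calendar$cell_col == cell_col &
    calendar$mirca_crop %in% mirca_crops & calendar$management == management
  sum(calendar$area[sel])
}

#' Distribute an annual harvested area over subcrop seasons
#'
#' Each subcrop `n` of the source calendar carries area
#' `(A_Mn / H_M) * H_G` in each of its growing months, where `H_M` is the
#' calendar-implied annual harvested area and `H_G` the annual harvested
#' area being disaggregated. A single-subcrop crop therefore carries the full
#' `H_G` throughout its season. Monthly crop totals are the sum over
#' subcrops overlapping the month.
#'
#' @param H_G Annual harvested area to disaggregate (1000 ha).
#' @param cal_entry Calendar rows for one (cell, crop-set, management):
#'   columns `subcrop`, `start_month`, `end_month`, `area`.
#' @return A tibble `subcrop`, `month`, `area` (one row per subcrop x
#'   growing month).
#' @export
scale_subcrops <- function(H_G, cal_entry) {
  H_M <- sum(cal_entry$area)
  if (nrow(cal_entry) == 0L || H_M <= 0) {
    stop("no calendar: source cell has no growing area for this crop; ",
         "apply the nearest-cell fallback first")
  }
  purrr::pmap_dfr(
    cal_entry[, c("subcrop", "start_month", "end_month", "area")],
    function(subcrop, start_month, end_month, area) {
      tibble::tibble(subcrop = subcrop,
                     month = season_months(start_month, end_month),
                     area = (area / H_M) * H_G)
    }
  )
}

#' Nearest cell holding a calendar for a crop
#'
#' When a cell has annual harvested area for a crop but no calendar for the
#' matching MIRCA crop (within the same management), the calendar is borrowed
#' from the great-circle-nearest cell (between cell centers) that has one.
#' Ties are broken by row, then column order.
#'
#' @param candidates Tibble of occupied cells: `cell_row`, `cell_col`.
#' @param cell_row,cell_col The cell needing a donor.
#' @param grid A `crop_grid` supplying the georeference.
#' @return A one-row tibble `cell_row`, `cell_col`, `distance_m`.
#' @export
find_nearest_source_cell <- function(candidates, cell_row, cell_col, grid) {
  if (nrow(candidates) == 0L) stop("no donor calendar: crop absent everywhere")
  p0 <- c(cell_center_lon(cell_col, grid), cell_center_lat(cell_row, grid))
  pts <- cbind(cell_center_lon(candidates$cell_col, grid),
               cell_center_lat(candidates$cell_row, grid))
  d <- geosphere::distHaversine(p0, pts)
  ord <- order(signif(d, 12), candidates$cell_row, candidates$cell_col)[1]
  tibble::tibble(cell_row = candidates$cell_row[ord],
                 cell_col = candidates$cell_col[ord],
                 distance_m = d[ord])
}

#' Truncate a cell-month to 99% of the cell area by removal order
#'
#' If the summed physical crop area of a cell-month exceeds 99% of the cell
#' area (at least 1% of land is retained for infrastructure and other
#' cover), area is removed crop by crop: all rainfed crops in ascending
#' removal order first, then all irrigated crops in ascending removal order,
#' zeroing each crop in turn and partially reducing the last one touched
#' until the total fits. Ties in removal order break alphabetically by crop
#' name. Irrigated area is therefore untouched unless every rainfed crop in
#' the cell-month has been zeroed.
#'
#' @param areas Tibble `gaez_crop`, `management`, `area` (1000 ha) for one
#'   cell-month.
#' @param cell_area Cell area (1000 ha).
#' @param orders Tibble `gaez_crop`, `removal_order` (1 = removed first).
#' @param cap_fraction Default 0.99.
#' @return A list: `areas` (input tibble with truncated `area`), `removed`
#'   (total area removed).
#' @export
cap_monthly_cell <- function(areas, cell_area, orders, cap_fraction = 0.99) {
  stopifnot(all(areas$area >= 0))
  limit <- cap_fraction * cell_area
  excess <- sum(areas$area) - limit
  if (excess <= 0) return(list(areas = areas, removed = 0))

  ord_tbl <- areas |>
    dplyr::left_join(orders, by = "gaez_crop") |>
    dplyr::mutate(.row = dplyr::row_number())
  if (anyNA(ord_tbl$removal_order)) {
    stop("no removal order for crop(s): ",
         paste(unique(ord_tbl$gaez_crop[is.na(ord_tbl$removal_order)]),
               collapse = ", "))
  }
  seq_idx <- order(ord_tbl$management != "Rainfed",
                   ord_tbl$removal_order, ord_tbl$gaez_crop)
  out <- areas$area
  removed <- 0
  for (i in seq_idx) {
    if (excess <= 0) break
    take <- min(out[i], excess)
    out[i] <- out[i] - take
    excess <- excess - take
    removed <- removed + take
  }
  areas$area <- out
  list(areas = areas, removed = removed)
}

#' Disaggregate annual harvested area into monthly physical crop area
#'
#' For every GAEZ crop and management with any positive annual harvested
#' area (all-zero layers, e.g. irrigated cassava, emit nothing), each cell's
#' annual area is spread over the matched MIRCA crop's subcrop seasons,
#' borrowing the calendar from the nearest occupied cell (same management)
#' where the cell itself lacks one. Multi-match categories pool the subcrop
#' lists of both MIRCA crops. Each cell-month is then truncated to 99% of
#' the cell area by removal order, with all subcrops of a crop scaled
#' together by the crop's post-removal fraction.
#'
#' @param annual_H Nested list `[[crop]][[management]]` of `crop_grid`
#'   harvested-area layers (e.g. `run_annual_update()$H`).
#' @param calendar Calendar tibble (see [mirca_annual_harvested_area()]).
#' @param matches MIRCA match tibble from [read_mirca_matches()].
#' @param cap_fraction Cell-area cap, default 0.99.
#' @return A list:
#'   `months` (tibble `cell_row`, `cell_col`, `gaez_crop`, `management`,
#'   `subcrop`, `month`, `area` after truncation), `pre_cap` (same before
#'   truncation), `cubes` (nested list `[[crop]][[management]][[subcrop]]`
#'   of [monthly_cube()] objects), `removal` (per-month totals and the
#'   maximum monthly removed area with its share of that month's physical
#'   cropland), `donors` (tibble of borrowed calendars with distances).
#' @export
run_monthly <- function(annual_H, calendar, matches = read_mirca_matches(),
                        cap_fraction = 0.99) {
  geo_ref <- annual_H[[1]][[1]]
  orders <- matches |>
    dplyr::select("gaez_crop", "removal_order")

  rows <- list()
  donors <- list()
  for (cr in names(annual_H)) {
    match <- lookup_mirca_match(cr, matches)
    mirca <- match$mirca_crops[[1]]
    for (m in names(annual_H[[cr]])) {
      vals <- annual_H[[cr]][[m]]$values
      idx <- which(!is.na(vals) & vals > 0, arr.ind = TRUE)
      dimnames(idx) <- NULL
      if (nrow(idx) == 0L) next  # all-zero layer: emit nothing

      cal <- calendar |>
        dplyr::filter(.data$mirca_crop %in% mirca, .data$management == m,
                      .data$area > 0) |>
        dplyr::arrange(.data$mirca_crop, .data$subcrop) |>
        dplyr::mutate(key = paste(.data$cell_row, .data$cell_col, sep = ":"),
                      months = purrr::map2(.data$start_month,
                                           .data$end_month, season_months))
      occupied <- cal |>
        dplyr::distinct(.data$cell_row, .data$cell_col)

      cells <- tibble::tibble(cell_row = idx[, 1], cell_col = idx[, 2],
                              H_G = vals[idx]) |>
        dplyr::mutate(key = paste(.data$cell_row, .data$cell_col, sep = ":"))

      # nearest-cell fallback for cells without a calendar (same management)
      missing <- which(!cells$key %in% cal$key)
      src_key <- cells$key
      for (j in missing) {
        donor <- find_nearest_source_cell(occupied, cells$cell_row[j],
                                          cells$cell_col[j], geo_ref)
        src_key[j] <- paste(donor$cell_row, donor$cell_col, sep = ":")
        donors[[length(donors) + 1L]] <- dplyr::mutate(
          donor, gaez_crop = cr, management = m,
          cell_row_to = cells$cell_row[j], cell_col_to = cells$cell_col[j],
          .before = 1)
      }
      cells$src_key <- src_key

      ent <- cal |>
        dplyr::group_by(.data$key) |>
        dplyr::mutate(H_M = sum(.data$area),
                      subcrop = dplyr::row_number()) |>
        dplyr::ungroup() |>
        dplyr::select(src_key = "key", "subcrop", "months", "area", "H_M")
      expanded <- cells |>
        dplyr::inner_join(ent, by = "src_key",
                          relationship = "many-to-many") |>
        dplyr::mutate(area = (.data$area / .data$H_M) * .data$H_G,
                      gaez_crop = cr, management = m) |>
        dplyr::select("cell_row", "cell_col", "gaez_crop", "management",
                      "subcrop", "months", "area") |>
        tidyr::unnest_longer("months", values_to = "month") |>
        dplyr::select("cell_row", "cell_col", "gaez_crop", "management",
                      "subcrop", "month", "area")
      rows[[length(rows) + 1L]] <- expanded
    }
  }
  pre_cap <- dplyr::bind_rows(rows)
  if (nrow(pre_cap) == 0L) {
    stop("no positive annual harvested area in any layer")
  }

  capped <- cap_monthly_table(pre_cap, geo_ref, orders, cap_fraction)
  cubes <- months_to_cubes(capped$months, geo_ref)
  list(months = capped$months, pre_cap = pre_cap, cubes = cubes,
       removal = capped$removal,
       donors = if (length(donors)) dplyr::bind_rows(donors) else
         tibble::tibble())
}

# Apply the monthly cap to the long table of subcrop areas.
cap_monthly_table <- function(months_df, geo_ref, orders, cap_fraction) {
  areas_row <- cell_area(seq_len(nrow(geo_ref$values)), geo_ref)
  cell_tot <- months_df |>
    dplyr::group_by(.data$cell_row, .data$cell_col, .data$month) |>
    dplyr::summarise(total = sum(.data$area), .groups = "drop") |>
    dplyr::mutate(cell_area = areas_row[.data$cell_row])

  over <- cell_tot |>
    dplyr::filter(.data$total > cap_fraction * .data$cell_area + 1e-12)

  per_month_total <- cell_tot |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(total_area = sum(.data$total), .groups = "drop")

  if (nrow(over) == 0L) {
    removal <- per_month_total |>
      dplyr::mutate(removed = 0)
    return(list(months = months_df,
                removal = list(per_month = removal, max_removed = 0,
                               max_removed_share = 0)))
  }

  months_df <- dplyr::mutate(months_df, .scale = 1)
  removed_by_month <- stats::setNames(numeric(12), 1:12)
  for (j in seq_len(nrow(over))) {
    rw <- over$cell_row[j]; cl <- over$cell_col[j]; mo <- over$month[j]
    sel <- months_df$cell_row == rw & months_df$cell_col == cl &
      months_df$month == mo
    crop_areas <- months_df[sel, ] |>
      dplyr::group_by(.data$gaez_crop, .data$management) |>
      dplyr::summarise(area = sum(.data$area), .groups = "drop")
    res <- cap_monthly_cell(crop_areas, over$cell_area[j], orders,
                            cap_fraction)
    frac <- res$areas |>
      dplyr::mutate(keep = ifelse(crop_areas$area > 0,
                                  .data$area / crop_areas$area, 1)) |>
      dplyr::select("gaez_crop", "management", "keep")
    sub <- months_df[sel, c("gaez_crop", "management")] |>
      dplyr::left_join(frac, by = c("gaez_crop", "management"))
    months_df$.scale[sel] <- sub$keep
    months_df$area[sel] <- months_df$area[sel] * sub$keep
    months_df$.scale[sel] <- 1
    removed_by_month[[mo]] <- removed_by_month[[mo]] + res$removed
  }
  months_df$.scale <- NULL

  removal <- per_month_total |>
    dplyr::mutate(removed = unname(removed_by_month[as.character(.data$month)]))
  max_i <- which.max(removal$removed)
  list(months = months_df,
       removal = list(
         per_month = removal,
         max_removed = removal$removed[max_i],
         max_removed_share = removal$removed[max_i] /
           removal$total_area[max_i]
       ))
}

#' Monthly physical-area cube
#'
#' Twelve monthly layers of physical crop area for one (crop, subcrop,
#' management), sharing a `crop_grid` georeference.
#'
#' @param values Numeric array `rows x cols x 12` (1000 ha; `NA` = no-data).
#' @param geo A `crop_grid` supplying the georeference.
#' @param crop,management,subcrop Identity of the cube.
#' @return An object of class `monthly_cube`.
#' @export
monthly_cube <- function(values, geo, crop = NA_character_,
                         management = NA_character_, subcrop = NA_integer_) {
  stopifnot(length(dim(values)) == 3L, dim(values)[3] == 12L)
  structure(list(values = values, west = geo$west, north = geo$north,
                 cellsize = geo$cellsize, crop = crop,
                 management = management, subcrop = subcrop),
            class = "monthly_cube")
}

#' @export
print.monthly_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<monthly_cube> %s / subcrop %s / %s: %d x %d x 12\n",
              x$crop, x$subcrop, x$management, d[1], d[2]))
  cat("  monthly totals (1000 ha):",
      paste(signif(apply(x$values, 3, sum, na.rm = TRUE), 4), collapse = " "),
      "\n")
  invisible(x)
}

# Materialize cubes from the long monthly table.
months_to_cubes <- function(months_df, geo_ref) {
  d <- dim(geo_ref$values)
  cubes <- list()
  combos <- months_df |>
    dplyr::distinct(.data$gaez_crop, .data$management, .data$subcrop)
  for (j in seq_len(nrow(combos))) {
    cr <- combos$gaez_crop[j]; m <- combos$management[j]
    n <- combos$subcrop[j]
    sub <- months_df |>
      dplyr::filter(.data$gaez_crop == cr, .data$management == m,
                    .data$subcrop == n)
    a <- array(0, c(d[1], d[2], 12L))
    a[cbind(sub$cell_row, sub$cell_col, sub$month)] <- sub$area
    a[is.na(geo_ref$values)] <- NA_real_  # recycles over months
    cubes[[cr]][[m]][[n]] <- monthly_cube(a, geo_ref, cr, m, n)
  }
  cubes
}
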