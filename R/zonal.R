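#' Zonal sums of a gridded layer
#'
#' Aggregates per-cell values over zones (administrative units, hydrologic
#' basins, countries). Cells carrying data but no zone are reported under
#' zone `NA` so that mass is conserved: the zone totals plus the unzoned
#' total equal the global sum.
#'
#' @param layer A `crop_grid`.
#' @param zones Either a matrix of zone identifiers with the same shape as
#'   the layer (`NA` = unzoned), or a tibble `cell_row`, `cell_col`, `zone`.
#' @return A tibble `zone`, `total`, sorted by zone, with an `NA` zone row
#'   for unzoned data cells (if any).
#' @export
zonal_sum <- function(layer, zones) {
  v <- layer$values
  if (is.data.frame(zones)) {
    zm <- matrix(NA, nrow(v), ncol(v))
    zm[cbind(zones$cell_row, zones$cell_col)] <- zones$zone
    zones <- zm
  }
  if (!identical(dim(zones), dim(v))) {
    stop("zone map shape does not match the layer")
  }
  keep <- !is.na(v)
  if (!any(keep)) return(tibble::tibble(zone = numeric(0), total = numeric(0)))
  tibble::tibble(zone = zones[keep], value = v[keep]) |>
    dplyr::group_by(.data$zone) |>
    dplyr::summarise(total = sum(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$zone)
}

#' Compare two zone-total tables by linear regression
#'
#' Ordinary least squares (with intercept) of `a` on `b` over the shared
#' zones. A slope below 1 means `a` under-reports `b`. The RMSE is the
#' root-mean-square residual of the fit.
#'
#' @param a,b Tibbles `zone`, `total` (e.g. from [zonal_sum()]).
#' @return A `cropland_comparison` object with fields `r2`, `slope`,
#'   `intercept`, `rmse`, `n_zones`, and the fitted data.
#' @export
compare_tables <- function(a, b) {
  joined <- dplyr::inner_join(a, b, by = "zone", suffix = c("_a", "_b")) |>
    dplyr::filter(!is.na(.data$zone))
  if (nrow(joined) < 2L) stop("need at least 2 shared zones to compare")
  fit <- stats::lm(total_a ~ total_b, data = joined)
  # identical tables fit perfectly; the summary warning is expected there
  s <- suppressWarnings(summary(fit))
  structure(list(
    r2 = s$r.squared,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    rmse = sqrt(mean(stats::residuals(fit)^2)),
    n_zones = nrow(joined),
    data = joined,
    fit = fit
  ), class = "cropland_comparison")
}

#' @export
print.cropland_comparison <- function(x, ...) {
  cat(sprintf(
    "<cropland_comparison> %d zones: r2 = %.4g, slope = %.4g, RMSE = %.4g\n",
    x$n_zones, x$r2, x$slope, x$rmse))
  invisible(x)
}

#' Cropland extent bounds from monthly and annual layers
#'
#' Physical cropland extent is bounded by two re-use assumptions. The
#' minimum extent assumes maximum re-use of land across seasons: the largest
#' monthly total growing area in each cell. The maximum extent assumes no
#' re-use: the annual harvested area summed over crops, capped by the cell
#' area. Per cell, minimum <= maximum <= cell area.
#'
#' @param months Long monthly tibble from [run_monthly()] (`cell_row`,
#'   `cell_col`, `month`, `area`).
#' @param annual_H Nested list `[[crop]][[management]]` of harvested-area
#'   `crop_grid`s.
#' @param geo A `crop_grid` supplying the georeference.
#' @return A list: `per_cell` tibble (`cell_row`, `cell_col`, `min_extent`,
#'   `max_extent`, `cell_area`), and global totals `min_total`, `max_total`
#'   (1000 ha).
#' @export
cropland_extent_bounds <- function(months, annual_H, geo) {
  min_ext <- months |>
    dplyr::group_by(.data$cell_row, .data$cell_col, .data$month) |>
    dplyr::summarise(monthly = sum(.data$area), .groups = "drop_last") |>
    dplyr::summarise(min_extent = max(.data$monthly), .groups = "drop")

  d <- dim(geo$values)
  ann <- matrix(0, d[1], d[2])
  for (cr in names(annual_H)) for (m in names(annual_H[[cr]])) {
    v <- annual_H[[cr]][[m]]$values
    ann <- ann + ifelse(is.na(v), 0, v)
  }
  areas_row <- cell_area(seq_len(d[1]), geo)

  per_cell <- min_ext |>
    dplyr::mutate(
      cell_area = areas_row[.data$cell_row],
      max_extent = pmin(ann[cbind(.data$cell_row, .data$cell_col)],
                        .data$cell_area)
    ) |>
    dplyr::select("cell_row", "cell_col", "min_extent", "max_extent",
                  "cell_area")
  list(per_cell = per_cell,
       min_total = sum(per_cell$min_extent),
       max_total = sum(per_cell$max_extent))
}

#' Harvested-area comparison report against national statistics
#'
#' Compares gridded harvested-area totals with FAOSTAT-style reported 2015
#' values, by crop (summed globally) and by country (summed over crops,
#' restricted through the cell fractions). Rows are sorted by descending
#' gridded total, as in the published comparison tables.
#'
#' @param annual_H Nested list `[[crop]][[management]]` of harvested-area
#'   `crop_grid`s.
#' @param fractions Cell-fraction tibble.
#' @param stats FAOSTAT-style tibble (`area_code`, `item_code`, `element`,
#'   `year`, `value`; harvested area in ha).
#' @param concordance From [read_crop_concordance()].
#' @param by `"crop"` or `"country"`.
#' @return A tibble with gridded and statistic totals (1000 ha), their
#'   difference and percent difference, plus `pct_label` formatted to one
#'   significant figure when the difference is below 1%.
#' @export
harvested_area_report <- function(annual_H, fractions, stats,
                                  concordance = read_crop_concordance(),
                                  by = c("crop", "country")) {
  by <- match.arg(by)
  fao15 <- stats |>
    dplyr::filter(.data$element == "area_harvested", .data$year == 2015L) |>
    dplyr::inner_join(dplyr::select(concordance, "faostat_code", "gaez_crop"),
                      by = c(item_code = "faostat_code"))

  grid_rows <- list()
  for (cr in names(annual_H)) {
    for (m in names(annual_H[[cr]])) {
      v <- annual_H[[cr]][[m]]$values
      per_country <- fractions |>
        dplyr::mutate(h = v[cbind(.data$cell_row, .data$cell_col)] *
                        .data$fraction) |>
        dplyr::group_by(.data$adm0_code) |>
        dplyr::summarise(gridded = sum(.data$h, na.rm = TRUE),
                         .groups = "drop") |>
        dplyr::mutate(gaez_crop = cr)
      grid_rows[[length(grid_rows) + 1L]] <- per_country
    }
  }
  gridded <- dplyr::bind_rows(grid_rows)

  if (by == "crop") {
    g <- gridded |>
      dplyr::group_by(.data$gaez_crop) |>
      dplyr::summarise(gridded_kha = sum(.data$gridded), .groups = "drop")
    f <- fao15 |>
      dplyr::group_by(.data$gaez_crop) |>
      dplyr::summarise(statistic_kha = sum(.data$value) / 1000,
                       .groups = "drop")
    out <- dplyr::full_join(g, f, by = "gaez_crop")
  } else {
    g <- gridded |>
      dplyr::group_by(adm0_code = .data$adm0_code) |>
      dplyr::summarise(gridded_kha = sum(.data$gridded), .groups = "drop")
    f <- fao15 |>
      dplyr::group_by(adm0_code = .data$area_code) |>
      dplyr::summarise(statistic_kha = sum(.data$value) / 1000,
                       .groups = "drop")
    out <- dplyr::full_join(g, f, by = "adm0_code")
  }
  out |>
    dplyr::mutate(
      gridded_kha = dplyr::coalesce(.data$gridded_kha, 0),
      statistic_kha = dplyr::coalesce(.data$statistic_kha, 0),
      difference_kha = .data$gridded_kha - .data$statistic_kha,
      pct_difference = ifelse(.data$statistic_kha > 0,
                              100 * .data$difference_kha / .data$statistic_kha,
                              NA_real_),
      pct_label = format_pct_diff(.data$pct_difference)
    ) |>
    dplyr::arrange(dplyr::desc(.data$gridded_kha))
}

#' Format a percent difference as in the published comparison tables
#'
#' Differences below 1% in magnitude are reported to one significant figure;
#' larger differences are rounded to the nearest whole percent. A leading
#' `+` marks positive differences.
#'
#' @param pct Numeric vector of percent differences.
#' @return Character vector.
#' @export
format_pct_diff <- function(pct) {
  out <- ifelse(abs(pct) < 1,
                formatC(signif(pct, 1), format = "fg", flag = "+"),
                formatC(round(pct), format = "d", flag = "+"))
  out[is.na(pct)] <- NA_character_
  out
}
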