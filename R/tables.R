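#' Read and write FAOSTAT-style statistics tables
#'
#' Long CSV with columns `area_code`, `item_code`, `element`
#' (`area_harvested` in ha, `production` in tonnes, `stocks` in head),
#' `year`, `value` and optionally `unit`. The reader is tolerant of missing
#' rows (missing country/year combinations are simply absent) and drops
#' rows with no value.
#'
#' @param path File path.
#' @return A tibble in reader layout.
#' @export
read_faostat_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    area_code = readr::col_integer(),
    item_code = readr::col_integer(),
    element = readr::col_character(),
    year = readr::col_integer(),
    value = readr::col_double(),
    .default = readr::col_character()
  ))
  req <- c("area_code", "item_code", "element", "year", "value")
  if (!all(req %in% names(df))) {
    stop("statistics table must have columns ", paste(req, collapse = ", "))
  }
  tibble::as_tibble(dplyr::filter(df, !is.na(.data$value)))
}

#' @rdname read_faostat_csv
#' @param stats Tibble in reader layout.
#' @export
write_faostat_csv <- function(stats, path) {
  readr::write_csv(stats, path)
  invisible(path)
}

#' Read and write cell-fraction tables
#'
#' Delimited text mapping grid cells to administrative units: columns
#' `cell_row`, `cell_col`, `adm0_code`, `fraction`. Fractions per cell must
#' sum to at most 1.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_cell_fractions <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    cell_row = readr::col_integer(),
    cell_col = readr::col_integer(),
    adm0_code = readr::col_integer(),
    fraction = readr::col_double()
  ))
  bad <- df |>
    dplyr::group_by(.data$cell_row, .data$cell_col) |>
    dplyr::summarise(s = sum(.data$fraction), .groups = "drop") |>
    dplyr::filter(.data$s > 1 + 1e-9)
  if (nrow(bad) > 0L) {
    stop("cell fractions sum to more than 1 in ", nrow(bad), " cell(s)")
  }
  if (any(df$fraction <= 0)) stop("cell fractions must be positive")
  tibble::as_tibble(df)
}

#' @rdname read_cell_fractions
#' @param fractions Tibble in reader layout.
#' @export
write_cell_fractions <- function(fractions, path) {
  readr::write_tsv(fractions, path)
  invisible(path)
}

#' Read and write subcrop calendar tables
#'
#' Delimited text per (cell, MIRCA crop, management, subcrop): columns
#' `cell_row`, `cell_col`, `mirca_crop`, `management`, `subcrop`,
#' `start_month`, `end_month`, `area` (1000 ha; the subcrop's physical area,
#' constant over its growing months). Seasons may wrap across December.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_calendar <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    cell_row = readr::col_integer(),
    cell_col = readr::col_integer(),
    mirca_crop = readr::col_character(),
    management = readr::col_character(),
    subcrop = readr::col_integer(),
    start_month = readr::col_integer(),
    end_month = readr::col_integer(),
    area = readr::col_double()
  ))
  stopifnot(all(df$start_month %in% 1:12), all(df$end_month %in% 1:12),
            all(df$area >= 0))
  tibble::as_tibble(df)
}

#' @rdname read_calendar
#' @param calendar Tibble in reader layout.
#' @export
write_calendar <- function(calendar, path) {
  readr::write_tsv(calendar, path)
  invisible(path)
}

#' Adapt a MIRCA-style condensed crop calendar
#'
#' Converts the condensed cropping-calendar layout (one row per cell and
#' subcrop, columns for crop class, area and start/end months, cells
#' addressed by lat/lon) into the calendar layout used here. Crop classes
#' are mapped to MIRCA crop names via `crop_names`; classes above
#' `length(crop_names)` are irrigated/rainfed duplicates per the MIRCA
#' convention (classes 1..26 irrigated, 27..52 rainfed).
#'
#' @param df A data frame with columns `lat`, `lon`, `crop_class`,
#'   `subcrop`, `area_ha`, `start_month`, `end_month`.
#' @param grid A `crop_grid` defining the target cell addressing.
#' @param crop_names Character vector of MIRCA crop names in class order.
#' @return A calendar tibble (area converted from ha to 1000 ha).
#' @export
adapt_condensed_calendar <- function(df, grid, crop_names) {
  n <- length(crop_names)
  stopifnot(all(df$crop_class >= 1), all(df$crop_class <= 2 * n))
  tibble::tibble(
    cell_row = as.integer(round((grid$north - df$lat) / grid$cellsize + 0.5)),
    cell_col = as.integer(round((df$lon - grid$west) / grid$cellsize + 0.5)),
    mirca_crop = crop_names[(df$crop_class - 1L) %% n + 1L],
    management = ifelse(df$crop_class <= n, "Irrigated", "Rainfed"),
    subcrop = as.integer(df$subcrop),
    start_month = as.integer(df$start_month),
    end_month = as.integer(df$end_month),
    area = df$area_ha / 1000
  )
}

#' Write or read a full synthetic-world bundle on disk
#'
#' Persists a [generate_world()] bundle in the exact external formats the
#' package reads: 2010 grids as float32 GeoTIFFs (named by the published
#' template with `GAEZAct2010` in place of the 2015 prefix), statistics as
#' FAOSTAT-style CSV, livestock as CSV, fractions/calendar/registry as TSV.
#'
#' @param world A [generate_world()] bundle.
#' @param dir Target directory.
#' @return `write_world_bundle()`: `dir`, invisibly; `read_world_bundle()`:
#'   a bundle list ready for [run_annual_update()] (ground truth is not
#'   persisted).
#' @export
write_world_bundle <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cr in names(world$h2010)) {
    for (m in names(world$h2010[[cr]])) {
      write_raster(world$h2010[[cr]][[m]], file.path(
        dir, sprintf("GAEZAct2010_HarvArea_%s_%s.tif", cr, m)))
      write_raster(world$p2010[[cr]][[m]], file.path(
        dir, sprintf("GAEZAct2010_Production_%s_%s.tif", cr, m)))
    }
  }
  write_faostat_csv(world$stats, file.path(dir, "faostat_stats.csv"))
  if (!is.null(world$livestock)) {
    readr::write_csv(world$livestock, file.path(dir, "livestock.csv"))
  }
  write_cell_fractions(world$fractions, file.path(dir, "cell_fractions.tsv"))
  write_calendar(world$calendar, file.path(dir, "calendar.tsv"))
  readr::write_tsv(world$registry, file.path(dir, "special_regions.tsv"))
  if (!is.null(world$splits)) {
    readr::write_tsv(world$splits, file.path(dir, "country_splits.tsv"))
  }
  writeLines(paste(names(world$h2010), collapse = "\t"),
             file.path(dir, "crops.tsv"))
  invisible(dir)
}

#' @rdname write_world_bundle
#' @export
read_world_bundle <- function(dir) {
  crops <- strsplit(readLines(file.path(dir, "crops.tsv"))[1], "\t")[[1]]
  h2010 <- list(); p2010 <- list()
  for (cr in crops) {
    for (m in c("Irrigated", "Rainfed")) {
      h2010[[cr]][[m]] <- read_raster(file.path(
        dir, sprintf("GAEZAct2010_HarvArea_%s_%s.tif", cr, m)))
      p2010[[cr]][[m]] <- read_raster(file.path(
        dir, sprintf("GAEZAct2010_Production_%s_%s.tif", cr, m)))
    }
  }
  lv_path <- file.path(dir, "livestock.csv")
  sp_path <- file.path(dir, "country_splits.tsv")
  list(
    h2010 = h2010, p2010 = p2010,
    stats = read_faostat_csv(file.path(dir, "faostat_stats.csv")),
    livestock = if (file.exists(lv_path)) {
      tibble::as_tibble(readr::read_csv(lv_path, col_types = readr::cols(
        area_code = readr::col_integer(), species = readr::col_character(),
        year = readr::col_integer(), value = readr::col_double())))
    } else NULL,
    fractions = read_cell_fractions(file.path(dir, "cell_fractions.tsv")),
    calendar = read_calendar(file.path(dir, "calendar.tsv")),
    registry = tibble::as_tibble(
      readr::read_tsv(file.path(dir, "special_regions.tsv"),
                      col_types = readr::cols(
                        adm0_code = readr::col_integer(),
                        name = readr::col_character(),
                        kind = readr::col_character()))),
    splits = if (file.exists(sp_path)) {
      tibble::as_tibble(readr::read_tsv(
        sp_path, col_types = readr::cols(.default = readr::col_integer())))
    } else NULL,
    concordance = read_crop_concordance(),
    matches = read_mirca_matches(),
    geo = h2010[[1]][[1]]
  )
}
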