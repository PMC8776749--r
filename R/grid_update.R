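#' Apply country change ratios to a gridded 2010 layer
#'
#' Each cell is multiplied by the fraction-weighted mean of the ratios of the
#' administrative units sharing it: `sum_i f_i * r_i / sum_i f_i`. The
#' normalisation by `sum_i f_i` makes a coastal cell lying wholly in one
#' country receive that country's ratio rather than a land-fraction-shrunken
#' one, and preserves the identity update when all ratios are 1. Cells with
#' no fraction entries, and no-data cells, are left unchanged. Units present
#' in the fraction table but absent from the ratio table contribute ratio 1.0
#' with a warning.
#'
#' @param layer2010 A `crop_grid` (harvested area or production).
#' @param fractions Cell-fraction tibble: `cell_row`, `cell_col`,
#'   `adm0_code`, `fraction` (fractions per cell sum to <= 1).
#' @param ratios Change-ratio tibble from [build_ratio_table()].
#' @param crop GAEZ category name.
#' @param variable `"H"` (uses `rH`) or `"P"` (uses `rP`).
#' @return A `crop_grid` of updated 2015 values.
#' @export
apply_ratios <- function(layer2010, fractions, ratios, crop,
                         variable = c("H", "P")) {
  variable <- match.arg(variable)
  rcol <- if (variable == "H") "rH" else "rP"
  r <- ratios |>
    dplyr::filter(.data$gaez_crop == crop) |>
    dplyr::select("adm0_code", ratio = dplyr::all_of(rcol))

  fr <- dplyr::left_join(fractions, r, by = "adm0_code")
  if (anyNA(fr$ratio)) {
    miss <- unique(fr$adm0_code[is.na(fr$ratio)])
    warning("no change ratio for administrative unit(s) ",
            paste(miss, collapse = ", "), " (crop ", crop,
            "); using 1.0")
    fr$ratio[is.na(fr$ratio)] <- 1.0
  }
  fac <- fr |>
    dplyr::group_by(.data$cell_row, .data$cell_col) |>
    dplyr::summarise(
      factor = sum(.data$fraction * .data$ratio) / sum(.data$fraction),
      .groups = "drop"
    )

  vals <- layer2010$values
  idx <- cbind(fac$cell_row, fac$cell_col)
  vals[idx] <- vals[idx] * fac$factor
  out <- layer2010
  out$values <- vals
  out
}

#' Cap a cell's total crop harvested area at 99% of the cell area
#'
#' If the sum of all crop harvested areas in a cell exceeds 99% of the cell
#' area, all areas are reduced equally (proportional scaling, preserving the
#' crop mix) to fit within 99%.
#'
#' @param crop_areas Named numeric vector of per-crop areas (1000 ha).
#' @param cell_area Cell area (1000 ha).
#' @param cap_fraction Retained-land headroom, default 0.99.
#' @return Scaled vector of areas.
#' @export
cap_annual_cell <- function(crop_areas, cell_area, cap_fraction = 0.99) {
  stopifnot(all(crop_areas >= 0, na.rm = TRUE))
  tot <- sum(crop_areas, na.rm = TRUE)
  limit <- cap_fraction * cell_area
  if (tot > limit) crop_areas * (limit / tot) else crop_areas
}

#' Per-cell crop yield
#'
#' Yield is production over harvested area (1000 tonnes / 1000 ha = t/ha);
#' cells with zero harvested area get yield 0. No-data is preserved.
#'
#' @param P,H `crop_grid` layers sharing a grid.
#' @return A `crop_grid` of yields in t/ha.
#' @export
compute_yield <- function(P, H) {
  if (!same_geo(P, H)) stop("production and harvested-area grids differ")
  y <- ifelse(H$values > 0, P$values / H$values, 0)
  y[is.na(P$values) | is.na(H$values)] <- NA_real_
  out <- H
  out$values <- y
  out
}

#' Run the annual update: 2010 grids to 2015 grids plus yields
#'
#' Applies the country change ratios to every crop x management harvested
#' area and production layer, enforces the 99% cell-area cap on the combined
#' (all crops, both managements) harvested area of each cell by proportional
#' scaling, and derives yields. Also returns a conservation report of
#' achieved vs target per-country totals.
#'
#' @param inputs A bundle as produced by [generate_world()] (or assembled by
#'   hand): `h2010` and `p2010` are nested lists `[[crop]][[management]]` of
#'   `crop_grid`s, plus `fractions`, and a ratio table under `ratios` (or the
#'   raw statistics to build one).
#' @param ratios Optional precomputed ratio table; defaults to
#'   `inputs$ratios`.
#' @param cap_fraction Cell-area cap, default 0.99.
#' @return A list: `H`, `P`, `Y` (nested lists `[[crop]][[management]]` of
#'   `crop_grid`s, managements `Irrigated`/`Rainfed`), `conservation`
#'   (tibble `adm0_code`, `gaez_crop`, `management`, `target`, `achieved`,
#'   `rel_error`), `cap_scale` (a `crop_grid` of the applied per-cell scale
#'   factors).
#' @export
run_annual_update <- function(inputs, ratios = NULL, cap_fraction = 0.99) {
  ratios <- ratios %||% inputs$ratios
  crops <- names(inputs$h2010)
  mgmts <- c("Irrigated", "Rainfed")
  geo_ref <- inputs$h2010[[1]][[1]]
  for (cr in crops) for (m in mgmts) {
    if (!same_geo(inputs$h2010[[cr]][[m]], geo_ref))
      stop("grid shape mismatch in 2010 harvested-area layers")
  }

  H <- list(); P <- list()
  for (cr in crops) {
    H[[cr]] <- list(); P[[cr]] <- list()
    for (m in mgmts) {
      H[[cr]][[m]] <- apply_ratios(inputs$h2010[[cr]][[m]], inputs$fractions,
                                   ratios, cr, "H")
      P[[cr]][[m]] <- apply_ratios(inputs$p2010[[cr]][[m]], inputs$fractions,
                                   ratios, cr, "P")
    }
  }

  # cap on the combined harvested area of all crops and managements
  tot <- geo_ref$values * 0
  for (cr in crops) for (m in mgmts) {
    v <- H[[cr]][[m]]$values
    tot <- tot + ifelse(is.na(v), 0, v)
  }
  areas <- cell_area_grid(geo_ref)$values
  limit <- cap_fraction * areas
  scale <- ifelse(tot > limit, limit / tot, 1)
  scale[tot == 0] <- 1
  for (cr in crops) for (m in mgmts) {
    H[[cr]][[m]]$values <- H[[cr]][[m]]$values * scale
  }

  Y <- list()
  for (cr in crops) {
    Y[[cr]] <- list()
    for (m in mgmts) Y[[cr]][[m]] <- compute_yield(P[[cr]][[m]], H[[cr]][[m]])
  }

  conservation <- conservation_report(inputs, H, ratios)
  cap_scale <- geo_ref
  cap_scale$values <- scale
  list(H = H, P = P, Y = Y, conservation = conservation,
       cap_scale = cap_scale)
}

# Per-country achieved vs target 2015 harvested-area totals, restricting grid
# sums to each unit through the cell fractions.
conservation_report <- function(inputs, H, ratios) {
  fr <- inputs$fractions
  rows <- list()
  for (cr in names(H)) {
    rr <- ratios |> dplyr::filter(.data$gaez_crop == cr)
    for (m in names(H[[cr]])) {
      v10 <- inputs$h2010[[cr]][[m]]$values
      v15 <- H[[cr]][[m]]$values
      sums <- fr |>
        dplyr::mutate(
          h10 = v10[cbind(.data$cell_row, .data$cell_col)] * .data$fraction,
          h15 = v15[cbind(.data$cell_row, .data$cell_col)] * .data$fraction
        ) |>
        dplyr::group_by(.data$adm0_code) |>
        dplyr::summarise(h10 = sum(.data$h10, na.rm = TRUE),
                         h15 = sum(.data$h15, na.rm = TRUE),
                         .groups = "drop") |>
        dplyr::left_join(dplyr::select(rr, "adm0_code", "rH"),
                         by = "adm0_code") |>
        dplyr::mutate(
          gaez_crop = cr, management = m,
          target = .data$h10 * dplyr::coalesce(.data$rH, 1.0),
          achieved = .data$h15,
          rel_error = ifelse(.data$target > 0,
                             abs(.data$achieved - .data$target) / .data$target,
                             abs(.data$achieved - .data$target))
        ) |>
        dplyr::select("adm0_code", "gaez_crop", "management",
                      "target", "achieved", "rel_error")
      rows[[length(rows) + 1L]] <- sums
    }
  }
  dplyr::bind_rows(rows)
}
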