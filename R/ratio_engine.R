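#' Three-year mean centred on a reference year
#'
#' National statistics are averaged over a three-year window (2009-2011 for
#' "2010", 2014-2016 for "2015") to bridge missing country/year combinations
#' and damp reported outliers. Missing years inside the window are simply
#' dropped from the mean; a fully empty window yields `NA`.
#'
#' @param series A tibble with columns `year` and `value` (or a named numeric
#'   vector, names = years).
#' @param center_year Centre of the +/-1 year window.
#' @return Mean of the available values, or `NA_real_`.
#' @export
three_year_mean <- function(series, center_year) {
  if (is.numeric(series) && !is.data.frame(series)) {
    series <- tibble::tibble(year = as.integer(names(series)), value = unname(series))
  }
  v <- series$value[series$year %in% (center_year - 1L):(center_year + 1L)]
  v <- v[!is.na(v)]
  if (length(v) == 0L) NA_real_ else mean(v)
}

#' 2015/2010 change ratio with the zero/missing rule
#'
#' Ratio of the 2015-window value to the 2010-window value. If either value
#' is zero or unreported the ratio is 1.0 (no change). Vectorised.
#'
#' @param v2010,v2015 Window means (may be `NA`).
#' @return Positive ratio(s); 1.0 under the zero/missing rule.
#' @export
compute_change_ratio <- function(v2010, v2015) {
  if (any(v2010 < 0 | v2015 < 0, na.rm = TRUE)) {
    stop("invalid statistic: negative harvested area or production")
  }
  ok <- !is.na(v2010) & !is.na(v2015) & v2010 > 0 & v2015 > 0
  ifelse(ok, v2015 / v2010, 1.0)
}

#' Area-weighted aggregation of member-crop ratios to a GAEZ category
#'
#' Where several FAOSTAT crops map to one GAEZ category, their ratios are
#' combined by an average weighted by FAOSTAT year-2015 harvested area. All
#' weights zero (or missing) falls back to 1.0, the no-information default.
#'
#' @param ratios Numeric vector of member ratios.
#' @param weights Numeric vector of 2015 harvested areas (same length).
#' @return A single aggregated ratio.
#' @export
aggregate_to_gaez <- function(ratios, weights) {
  stopifnot(length(ratios) == length(weights), length(ratios) > 0L)
  weights[is.na(weights)] <- 0
  keep <- weights > 0 & !is.na(ratios)
  if (!any(keep)) return(1.0)
  sum(ratios[keep] * weights[keep]) / sum(weights[keep])
}

#' Fodder-crop change ratio from livestock herd sizes
#'
#' FAOSTAT no longer reports fodder-crop harvested area; the 2010-to-2015
#' change is taken as proportional to the change in national cattle plus
#' buffalo head counts, with the same three-year windows and zero/missing
#' rule as crops.
#'
#' @param livestock A tibble with columns `year` and `value` (head counts,
#'   already summed over species) or columns `species`, `year`, `value`.
#' @return A single ratio.
#' @export
fodder_ratio <- function(livestock) {
  if (is.null(livestock) || nrow(livestock) == 0L) return(1.0)
  totals <- livestock |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(value = sum(.data$value, na.rm = TRUE), .groups = "drop")
  compute_change_ratio(three_year_mean(totals, 2010L),
                       three_year_mean(totals, 2015L))
}

#' Split a parent country's pre-split statistics between successor states
#'
#' For countries that split during the study period (Sudan / South Sudan in
#' 2011), pre-split years are reported for the parent only. Each pre-split
#' value is apportioned to the successors by their shares in the first year
#' both reported (2012); if both successors report zero for a crop the value
#' is split 50/50.
#'
#' @param parent_values Named numeric vector (or tibble `key`,`value`) of the
#'   parent's values per series key (crop x element).
#' @param children_2012 A list of two named numeric vectors (or tibbles),
#'   one per successor, holding year-2012 values per series key.
#' @return A list of two named numeric vectors of virtual pre-split values.
#' @export
split_parent_country <- function(parent_values, children_2012) {
  as_vec <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$value, x$key) else x
  }
  p <- as_vec(parent_values)
  ch <- lapply(children_2012, as_vec)
  stopifnot(length(ch) == 2L)
  out <- lapply(ch, function(z) stats::setNames(numeric(length(p)), names(p)))
  for (k in names(p)) {
    a <- if (k %in% names(ch[[1]])) ch[[1]][[k]] else 0
    b <- if (k %in% names(ch[[2]])) ch[[2]][[k]] else 0
    if (is.na(a)) a <- 0
    if (is.na(b)) b <- 0
    shares <- if (a + b > 0) c(a, b) / (a + b) else c(0.5, 0.5)
    out[[1]][[k]] <- p[[k]] * shares[1]
    out[[2]][[k]] <- p[[k]] * shares[2]
  }
  out
}

# Apply country splits to a FAOSTAT-style long table: rows of the parent in
# pre-split years are replaced by apportioned rows for each child, using the
# children's year-2012 shares per (item_code, element).
apply_country_splits <- function(stats, splits) {
  if (is.null(splits) || nrow(splits) == 0L) return(stats)
  for (s in seq_len(nrow(splits))) {
    parent <- splits$parent[s]
    kids <- c(splits$child1[s], splits$child2[s])
    pre <- stats |> dplyr::filter(.data$area_code == parent)
    if (nrow(pre) == 0L) next
    key_of <- function(df) paste(df$item_code, df$element, sep = "|")
    shares12 <- lapply(kids, function(k) {
      d <- stats |> dplyr::filter(.data$area_code == k, .data$year == 2012L)
      stats::setNames(d$value, key_of(d))
    })
    parent_vec <- stats::setNames(pre$value, key_of(pre))
    # apportion row-wise: same key may recur across years, shares are per key
    split_one <- function(child_idx) {
      k <- key_of(pre)
      a <- unname(shares12[[1]][k]); a[is.na(a)] <- 0
      b <- unname(shares12[[2]][k]); b[is.na(b)] <- 0
      tot <- a + b
      share <- ifelse(tot > 0, (if (child_idx == 1L) a else b) / tot, 0.5)
      dplyr::mutate(pre, area_code = kids[child_idx],
                    value = .data$value * share)
    }
    stats <- dplyr::bind_rows(
      stats |> dplyr::filter(.data$area_code != parent),
      split_one(1L), split_one(2L)
    )
  }
  stats
}

#' Build the country x GAEZ-crop change-ratio table
#'
#' Runs the full national-statistics stage: country splits, three-year window
#' means, FAOSTAT-level ratios with the zero/missing rule, area-weighted
#' aggregation to the 26 GAEZ categories, the livestock-based fodder ratio,
#' and forcing of special-case regions (no-data islands, disputed areas) to
#' 1.0. Exactly 26 `(rH, rP)` pairs are produced per administrative unit.
#'
#' @param stats FAOSTAT-style tibble: `area_code`, `item_code`, `element`
#'   (`"area_harvested"` in ha, `"production"` in tonnes), `year`, `value`.
#' @param livestock Tibble `area_code`, `species`, `year`, `value`
#'   (head counts), or `NULL`.
#' @param concordance From [read_crop_concordance()].
#' @param registry Special regions tibble ([read_special_regions()]), or
#'   `NULL`.
#' @param splits Country-split tibble with columns `parent`, `child1`,
#'   `child2` (ADM0 codes), or `NULL`.
#' @param countries Optional integer vector of ADM0 codes that must appear in
#'   the result (e.g. every unit present in the cell-fraction table); units
#'   with no statistics and no registry entry get ratio 1.0 with a warning.
#' @return A tibble `adm0_code`, `gaez_crop`, `rH`, `rP` with 26 rows per
#'   unit.
#' @export
build_ratio_table <- function(stats, livestock = NULL,
                              concordance = read_crop_concordance(),
                              registry = NULL, splits = NULL,
                              countries = NULL) {
  crops <- unique(concordance$gaez_crop)
  stats <- apply_country_splits(stats, splits)

  stat_countries <- unique(stats$area_code)
  reg_countries <- if (is.null(registry)) integer() else registry$adm0_code
  split_parents <- if (is.null(splits)) integer() else splits$parent
  all_countries <- sort(unique(c(stat_countries, reg_countries,
                                 countries %||% integer())))
  all_countries <- setdiff(all_countries, split_parents)

  missing <- setdiff(all_countries, c(stat_countries, reg_countries))
  if (length(missing) > 0L) {
    warning("no statistics for administrative unit(s) ",
            paste(missing, collapse = ", "), "; change ratio set to 1.0")
  }

  # FAOSTAT-level window means and ratios
  win <- stats |>
    dplyr::filter(.data$element %in% c("area_harvested", "production")) |>
    dplyr::group_by(.data$area_code, .data$item_code, .data$element) |>
    dplyr::summarise(
      v2010 = three_year_mean(dplyr::pick("year", "value"), 2010L),
      v2015 = three_year_mean(dplyr::pick("year", "value"), 2015L),
      w2015 = {
        y15 <- .data$value[.data$year == 2015L & !is.na(.data$value)]
        if (length(y15) > 0L) y15[1] else NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(ratio = compute_change_ratio(.data$v2010, .data$v2015))

  # harvested-area weights apply to both rH and rP aggregation
  weights <- win |>
    dplyr::filter(.data$element == "area_harvested") |>
    dplyr::mutate(weight = dplyr::coalesce(.data$w2015, .data$v2015, 0)) |>
    dplyr::select("area_code", "item_code", "weight")

  mapped <- win |>
    dplyr::inner_join(dplyr::select(concordance, "faostat_code", "gaez_crop"),
                      by = c(item_code = "faostat_code")) |>
    dplyr::left_join(weights, by = c("area_code", "item_code"))

  agg <- mapped |>
    dplyr::group_by(.data$area_code, .data$gaez_crop, .data$element) |>
    dplyr::summarise(
      ratio = aggregate_to_gaez(.data$ratio,
                                dplyr::coalesce(.data$weight, 0)),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "element", values_from = "ratio")
  if (!"area_harvested" %in% names(agg)) agg$area_harvested <- NA_real_
  if (!"production" %in% names(agg)) agg$production <- NA_real_

  base <- tidyr::expand_grid(adm0_code = all_countries, gaez_crop = crops) |>
    dplyr::left_join(
      dplyr::rename(agg, adm0_code = "area_code",
                    rH = "area_harvested", rP = "production"),
      by = c("adm0_code", "gaez_crop")
    ) |>
    dplyr::mutate(rH = dplyr::coalesce(.data$rH, 1.0),
                  rP = dplyr::coalesce(.data$rP, 1.0))

  # fodder via livestock
  if ("Fodder_crop" %in% crops) {
    fodder <- tibble::tibble(
      adm0_code = all_countries,
      fr = vapply(all_countries, function(cc) {
        lv <- if (is.null(livestock)) NULL else
          dplyr::filter(livestock, .data$area_code == cc)
        fodder_ratio(lv)
      }, numeric(1))
    )
    base <- base |>
      dplyr::left_join(fodder, by = "adm0_code") |>
      dplyr::mutate(
        rH = ifelse(.data$gaez_crop == "Fodder_crop", .data$fr, .data$rH),
        rP = ifelse(.data$gaez_crop == "Fodder_crop", .data$fr, .data$rP)
      ) |>
      dplyr::select(-"fr")
  }

  # special-case regions: frozen at no change
  if (length(reg_countries) > 0L) {
    base <- base |>
      dplyr::mutate(
        rH = ifelse(.data$adm0_code %in% reg_countries, 1.0, .data$rH),
        rP = ifelse(.data$adm0_code %in% reg_countries, 1.0, .data$rP)
      )
  }

  dplyr::arrange(base, .data$adm0_code, .data$gaez_crop)
}
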