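#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a zone-comparison fit
#'
#' @param x A `cropland_comparison` from [compare_tables()].
#' @param ... Unused.
#' @return `tidy()`: one row per regression term (`term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`); `glance()`: a one-row summary
#'   (`r2`, `slope`, `intercept`, `rmse`, `n_zones`).
#' @export
tidy.cropland_comparison <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @rdname tidy.cropland_comparison
#' @export
glance.cropland_comparison <- function(x, ...) {
  tibble::tibble(r2 = x$r2, slope = x$slope, intercept = x$intercept,
                 rmse = x$rmse, n_zones = x$n_zones)
}

#' @rdname tidy.cropland_comparison
#' @param object A `cropland_comparison`.
#' @return `autoplot()`: a ggplot of paired zone totals with the 1:1 line
#'   (grey) and the fitted regression line.
#' @export
autoplot.cropland_comparison <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$total_b, y = .data$total_a)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = "reference zone total (1000 ha)",
                  y = "gridded zone total (1000 ha)",
                  subtitle = sprintf("r2 = %.3f, slope = %.3f, RMSE = %.3g",
                                     object$r2, object$slope, object$rmse)) +
    ggplot2::theme_minimal()
}

#' Plot a gridded layer
#'
#' @param object A `crop_grid`.
#' @param ... Unused.
#' @return A ggplot tile map of the non-missing cells.
#' @export
autoplot.crop_grid <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_tile(width = object$cellsize, height = object$cellsize) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "value") +
    ggplot2::theme_minimal()
}

#' Plot aggregate monthly physical area by subcrop
#'
#' Sums the monthly table over cells, keeping subcrops apart - the standard
#' view for multi-season crops (two rice subcrops show the two growing
#' seasons as separate peaks).
#'
#' @param months Long monthly tibble from [run_monthly()].
#' @param crop Optional GAEZ crop filter.
#' @param management Optional management filter.
#' @return A ggplot.
#' @export
plot_monthly_series <- function(months, crop = NULL, management = NULL) {
  df <- months
  if (!is.null(crop)) df <- dplyr::filter(df, .data$gaez_crop == crop)
  if (!is.null(management)) {
    df <- dplyr::filter(df, .data$management == management)
  }
  agg <- df |>
    dplyr::group_by(.data$gaez_crop, .data$subcrop, .data$month) |>
    dplyr::summarise(area = sum(.data$area), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$month, y = .data$area,
                                    colour = factor(.data$subcrop))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 1:12) +
    ggplot2::facet_wrap(ggplot2::vars(.data$gaez_crop), scales = "free_y") +
    ggplot2::labs(x = "month", y = "physical area (1000 ha)",
                  colour = "subcrop") +
    ggplot2::theme_minimal()
}
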