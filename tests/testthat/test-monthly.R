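make_cal <- function(...) {
  tibble::tibble(...)
}

test_that("calendar-implied annual harvested area sums subcrops", {
  cal <- make_cal(cell_row = c(3, 3, 5), cell_col = c(4, 4, 4),
                  mirca_crop = "Rice", management = "Rainfed",
                  subcrop = c(1L, 2L, 1L), start_month = c(1L, 6L, 2L),
                  end_month = c(5L, 10L, 6L), area = c(6, 4, 7))
  expect_equal(mirca_annual_harvested_area(cal, 3, 4, "Rice", "Rainfed"), 10)
  expect_equal(mirca_annual_harvested_area(cal, 9, 9, "Rice", "Rainfed"), 0)
  expect_equal(mirca_annual_harvested_area(cal, 5, 4, "Rice", "Rainfed"), 7)
  expect_equal(mirca_annual_harvested_area(cal, 3, 4, "Rice", "Irrigated"), 0)
})

test_that("annual area is spread over subcrop seasons in proportion", {
  ent <- make_cal(subcrop = 1:2, start_month = c(1L, 6L),
                  end_month = c(3L, 8L), area = c(6, 4))
  sc <- scale_subcrops(20, ent)
  expect_equal(unique(sc$area[sc$subcrop == 1]), 12)
  expect_equal(unique(sc$area[sc$subcrop == 2]), 8)
  expect_equal(sum(sc$area[sc$month == 2]), 12)
  expect_equal(sum(sc$area[sc$month == 7]), 8)
  expect_equal(sum(sc$area[sc$month == 5]), 0)

  single <- make_cal(subcrop = 1L, start_month = 4L, end_month = 9L, area = 3)
  sc1 <- scale_subcrops(11, single)
  expect_setequal(sc1$month, 4:9)
  expect_true(all(sc1$area == 11))

  wrap <- make_cal(subcrop = 1L, start_month = 11L, end_month = 2L, area = 5)
  scw <- scale_subcrops(7, wrap)
  expect_setequal(scw$month, c(11, 12, 1, 2))

  empty <- make_cal(subcrop = integer(), start_month = integer(),
                    end_month = integer(), area = numeric())
  expect_error(scale_subcrops(5, empty), "no calendar")
  zero <- make_cal(subcrop = 1L, start_month = 1L, end_month = 2L, area = 0)
  expect_error(scale_subcrops(5, zero), "no calendar")
})

test_that("season months handle wrap and reject bad input", {
  expect_equal(season_months(4, 9), 4:9)
  expect_equal(season_months(11, 2), c(11L, 12L, 1L, 2L))
  expect_equal(season_months(6, 6), 6L)
  expect_error(season_months(0, 5))
})

test_that("nearest donor cells match an exhaustive scan with (row, col) ties", {
  g <- tiny_grid(matrix(0, 36, 72))
  self <- tibble::tibble(cell_row = 10L, cell_col = 20L)
  expect_equal(find_nearest_source_cell(self, 10, 20, g)$cell_row, 10L)
  expect_equal(find_nearest_source_cell(self, 10, 20, g)$distance_m, 0)

  two <- tibble::tibble(cell_row = c(10L, 10L), cell_col = c(22L, 26L))
  expect_equal(find_nearest_source_cell(two, 10, 20, g)$cell_col, 22L)

  # equidistant east/west candidates: lower column wins
  sym <- tibble::tibble(cell_row = c(10L, 10L), cell_col = c(18L, 22L))
  expect_equal(find_nearest_source_cell(sym, 10, 20, g)$cell_col, 18L)

  expect_error(find_nearest_source_cell(sym[0, ], 10, 20, g),
               "no donor calendar")

  # property: agrees with an independent exhaustive scan
  sloc_dist <- function(r1, c1, r2, c2) {
    to <- pi / 180
    la1 <- cell_center_lat(r1, g) * to; lo1 <- cell_center_lon(c1, g) * to
    la2 <- cell_center_lat(r2, g) * to; lo2 <- cell_center_lon(c2, g) * to
    acos(pmin(1, pmax(-1, sin(la1) * sin(la2) +
                        cos(la1) * cos(la2) * cos(lo2 - lo1))))
  }
  withr::with_seed(21, {
    for (rep in 1:25) {
      cand <- tibble::tibble(cell_row = sample(36, 8, replace = TRUE),
                             cell_col = sample(72, 8, replace = TRUE)) |>
        dplyr::distinct()
      r0 <- sample(36, 1); c0 <- sample(72, 1)
      got <- find_nearest_source_cell(cand, r0, c0, g)
      d <- mapply(sloc_dist, cand$cell_row, cand$cell_col, r0, c0)
      best <- cand[order(signif(d, 10), cand$cell_row, cand$cell_col)[1], ]
      expect_equal(got$cell_row, best$cell_row)
      expect_equal(got$cell_col, best$cell_col)
    }
  })
})

test_that("monthly truncation removes rainfed crops first, by removal order", {
  ords <- orders_tbl()
  areas <- tibble::tibble(
    gaez_crop = c("Stimulants", "Wheat", "Wheat"),
    management = c("Rainfed", "Rainfed", "Irrigated"),
    area = c(10, 60, 40)
  )
  res <- cap_monthly_cell(areas, 100, ords)
  expect_equal(res$areas$area, c(0, 59, 40))  # Stimulants gone, wheat trimmed
  expect_equal(res$removed, 11)

  under <- dplyr::mutate(areas, area = c(10, 45, 40))
  res2 <- cap_monthly_cell(under, 100, ords)
  expect_equal(res2$areas$area, under$area)
  expect_equal(res2$removed, 0)

  solo <- tibble::tibble(gaez_crop = "Vegetables", management = "Rainfed",
                         area = 99.5)
  res3 <- cap_monthly_cell(solo, 100, ords)
  expect_equal(res3$areas$area, 99)
  expect_equal(res3$removed, 0.5)
})

test_that("monthly truncation equals the greedy oracle on random instances", {
  ords <- orders_tbl()
  crops <- gaez_crop_names()
  withr::with_seed(77, {
    for (i in 1:300) {
      n <- sample(1:6, 1)
      areas <- tibble::tibble(
        gaez_crop = sample(crops, n),
        management = sample(c("Rainfed", "Irrigated"), n, replace = TRUE),
        area = round(runif(n, 0, 40), 3)
      )
      ca <- runif(1, 30, 120)
      got <- cap_monthly_cell(areas, ca, ords)
      want <- cap_oracle(areas, ca, ords)
      expect_equal(got$areas$area, want$areas$area, tolerance = 1e-12)
      expect_equal(got$removed, want$removed, tolerance = 1e-12)
      expect_lte(sum(got$areas$area), 0.99 * ca + 1e-9)
      expect_true(all(got$areas$area <= areas$area + 1e-12))
    }
  })
})

test_that("monthly disaggregation is consistent with annual area pre-cap", {
  w <- default_world()
  mo <- default_monthly()
  ann <- default_annual()
  # per (cell, crop, mgmt): sum over subcrops of each subcrop's constant
  # area equals the annual harvested area
  per_sub <- mo$pre_cap |>
    dplyr::group_by(cell_row, cell_col, gaez_crop, management, subcrop) |>
    dplyr::summarise(a = max(area), lo = min(area), .groups = "drop")
  expect_equal(per_sub$a, per_sub$lo)  # constant across growing months
  tot <- per_sub |>
    dplyr::group_by(cell_row, cell_col, gaez_crop, management) |>
    dplyr::summarise(tot = sum(a), .groups = "drop")
  for (cr in names(ann$H)) {
    for (m in names(ann$H[[cr]])) {
      v <- ann$H[[cr]][[m]]$values
      sub <- dplyr::filter(tot, gaez_crop == cr, management == m)
      expect_equal(sub$tot, v[cbind(sub$cell_row, sub$cell_col)],
                   tolerance = 1e-9)
      n_pos <- sum(!is.na(v) & v > 0)
      expect_equal(nrow(sub), n_pos)
    }
  }
})

test_that("borrowed calendars come from the truth donor map", {
  w <- default_world()
  mo <- default_monthly()
  expect_gt(nrow(w$truth$donors), 0)
  got <- mo$donors |>
    dplyr::transmute(gaez_crop, management, to_row = cell_row_to,
                     to_col = cell_col_to, donor_row = cell_row,
                     donor_col = cell_col) |>
    dplyr::arrange(gaez_crop, management, to_row, to_col)
  want <- w$truth$donors |>
    dplyr::mutate(donor_row = as.integer(donor_row),
                  donor_col = as.integer(donor_col)) |>
    dplyr::arrange(gaez_crop, management, cell_row, cell_col)
  expect_equal(got$donor_row, want$donor_row)
  expect_equal(got$donor_col, want$donor_col)
  expect_equal(nrow(got), nrow(want))
})

test_that("two rice subcrops produce a bimodal aggregate monthly series", {
  mo <- default_monthly()
  rice <- mo$months |>
    dplyr::filter(gaez_crop == "Rice") |>
    dplyr::group_by(month) |>
    dplyr::summarise(area = sum(area), .groups = "drop") |>
    tidyr::complete(month = 1:12, fill = list(area = 0))
  # the two seasons (months 1-5 and 6-10) leave months 11-12 empty
  expect_gt(rice$area[rice$month == 3], 0)
  expect_gt(rice$area[rice$month == 8], 0)
  expect_equal(rice$area[rice$month %in% c(11, 12)], c(0, 0))
  # season areas differ (60/40 split), so the series has two distinct levels
  expect_false(isTRUE(all.equal(rice$area[rice$month == 3],
                                rice$area[rice$month == 8])))
})

test_that("multi-match categories pool the calendars of both MIRCA crops", {
  w <- default_world()
  mo <- default_monthly()
  oc <- mo$pre_cap |>
    dplyr::filter(gaez_crop == "Other_cereals")
  expect_gt(nrow(oc), 0)
  # pooled calendar entries exist under both Rye and Millet
  cal <- w$calendar |>
    dplyr::filter(mirca_crop %in% c("Rye", "Millet"))
  expect_setequal(unique(cal$mirca_crop), c("Rye", "Millet"))
})

test_that("monthly capping enforces the 99% law and protects irrigated area", {
  w <- stress_world()
  mo <- stress_monthly()
  geo <- w$geo
  areas_row <- cell_area(seq_len(nrow(geo$values)), geo)
  tot <- mo$months |>
    dplyr::group_by(cell_row, cell_col, month) |>
    dplyr::summarise(area = sum(area), .groups = "drop")
  expect_true(all(tot$area <= 0.99 * areas_row[tot$cell_row] + 1e-9))

  pre <- mo$pre_cap |>
    dplyr::group_by(cell_row, cell_col, month) |>
    dplyr::summarise(area = sum(area), .groups = "drop")
  over <- dplyr::filter(pre, area > 0.99 * areas_row[cell_row] + 1e-9)
  expect_gt(nrow(over), 0)  # the stress world does overflow pre-cap
  expect_gt(mo$removal$max_removed, 0)
  expect_lte(mo$removal$max_removed_share, 1)

  # truncation never increases area
  j <- dplyr::inner_join(
    mo$pre_cap, mo$months,
    by = c("cell_row", "cell_col", "gaez_crop", "management", "subcrop",
           "month"),
    suffix = c("_pre", "_post"))
  expect_true(all(j$area_post <= j$area_pre + 1e-12))

  # irrigated untouched unless all rainfed in the cell-month is zeroed
  per <- j |>
    dplyr::group_by(cell_row, cell_col, month, management) |>
    dplyr::summarise(pre = sum(area_pre), post = sum(area_post),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = management, values_from = c(pre, post),
                       values_fill = 0)
  touched_irr <- per$post_Irrigated < per$pre_Irrigated - 1e-9
  if (any(touched_irr)) {
    expect_true(all(per$post_Rainfed[touched_irr] < 1e-9))
  }
})
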