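test_that("zonal sums match a naive loop and conserve mass", {
  withr::with_seed(31, {
    m <- matrix(runif(36 * 72), 36, 72)
    m[sample(length(m), 300)] <- NA
    zones <- matrix(sample(c(NA, 1:5), 36 * 72, replace = TRUE), 36, 72)
  })
  g <- tiny_grid(m)
  zs <- zonal_sum(g, zones)

  # independent naive accumulation
  acc <- new.env()
  for (i in 1:36) for (j in 1:72) {
    if (is.na(m[i, j])) next
    z <- as.character(zones[i, j])
    acc[[z]] <- (acc[[z]] %||% 0) + m[i, j]
  }
  for (z in 1:5) {
    expect_equal(zs$total[!is.na(zs$zone) & zs$zone == z], acc[[as.character(z)]])
  }
  expect_equal(zs$total[is.na(zs$zone)], acc[["NA"]])
  expect_equal(sum(zs$total), sum(m, na.rm = TRUE), tolerance = 1e-12)

  # uniform layer over a 10-cell zone
  u <- matrix(NA_real_, 4, 5); z2 <- matrix(NA, 4, 5)
  u[1:2, 1:5] <- 1; z2[1:2, 1:5] <- 7
  expect_equal(zonal_sum(tiny_grid(u, 45), z2)$total, 10)

  empty <- tiny_grid(matrix(NA_real_, 4, 5), 45)
  expect_equal(nrow(zonal_sum(empty, z2)), 0)

  expect_error(zonal_sum(g, zones[1:10, ]), "shape")
})

test_that("zone-table regression matches the closed form", {
  t1 <- tibble::tibble(zone = 1:10, total = c(3, 8, 1, 9, 4, 7, 2, 6, 5, 10))
  same <- compare_tables(t1, t1)
  expect_equal(same$r2, 1)
  expect_equal(same$slope, 1)
  expect_equal(same$rmse, 0, tolerance = 1e-12)

  doubled <- compare_tables(dplyr::mutate(t1, total = total * 2), t1)
  expect_equal(doubled$slope, 2)
  expect_equal(doubled$r2, 1)

  withr::with_seed(41, {
    a <- tibble::tibble(zone = 1:30, total = runif(30, 0, 100))
    b <- tibble::tibble(zone = 1:30, total = a$total * 0.8 + rnorm(30, 0, 5))
  })
  cmp <- compare_tables(a, b)
  # textbook OLS of a on b
  x <- b$total; y <- a$total
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  resid <- y - (intercept + slope * x)
  expect_equal(cmp$slope, slope, tolerance = 1e-12)
  expect_equal(cmp$intercept, intercept, tolerance = 1e-12)
  expect_equal(cmp$r2, 1 - sum(resid^2) / sum((y - mean(y))^2),
               tolerance = 1e-12)
  expect_equal(cmp$rmse, sqrt(mean(resid^2)), tolerance = 1e-12)

  expect_error(compare_tables(t1[1, ], t1[1, ]), "at least 2")

  g <- glance(cmp)
  expect_equal(g$slope, cmp$slope)
  td <- tidy(cmp)
  expect_equal(nrow(td), 2)
})

test_that("extent bounds bracket physical cropland per cell", {
  geo <- tiny_grid(matrix(0, 36, 72))
  # worked example: two non-overlapping 5-unit seasons in one cell
  months <- dplyr::bind_rows(
    tibble::tibble(cell_row = 10L, cell_col = 10L, gaez_crop = "Rice",
                   management = "Rainfed", subcrop = 1L, month = 1:5,
                   area = 5),
    tibble::tibble(cell_row = 10L, cell_col = 10L, gaez_crop = "Rice",
                   management = "Rainfed", subcrop = 2L, month = 6:10,
                   area = 5)
  )
  hvals <- geo$values; hvals[10, 10] <- 10
  annual <- list(Rice = list(Rainfed = tiny_grid(hvals)))
  bb <- cropland_extent_bounds(months, annual, geo)
  expect_equal(bb$per_cell$min_extent, 5)
  expect_equal(bb$per_cell$max_extent, 10)

  # single one-season crop: min = max = annual area
  m1 <- dplyr::filter(months, subcrop == 1L)
  h1 <- geo$values; h1[10, 10] <- 5
  bb1 <- cropland_extent_bounds(m1, list(Rice = list(Rainfed = tiny_grid(h1))),
                                geo)
  expect_equal(bb1$per_cell$min_extent, bb1$per_cell$max_extent)
  expect_equal(bb1$min_total, 5)

  # annual total above the cell area is clamped to the cell area
  ca <- cell_area(10, geo)
  hbig <- geo$values; hbig[10, 10] <- ca * 1.2
  mbig <- dplyr::mutate(m1, area = ca * 0.5)
  bb2 <- cropland_extent_bounds(mbig,
                                list(Rice = list(Rainfed = tiny_grid(hbig))),
                                geo)
  expect_equal(bb2$per_cell$max_extent, ca)

  # on a full world run: min <= max <= cell area everywhere
  mo <- default_monthly()
  ann <- default_annual()
  bbw <- cropland_extent_bounds(mo$months, ann$H, default_world()$geo)
  expect_true(all(bbw$per_cell$min_extent <=
                    bbw$per_cell$max_extent + 1e-9))
  expect_true(all(bbw$per_cell$max_extent <=
                    bbw$per_cell$cell_area + 1e-9))
})

test_that("harvested-area reports reconcile grids with statistics", {
  w <- default_world()
  ann <- default_annual()
  # restrict to reporting units: registry islands and disputed areas carry
  # crop area but no statistics, so global crop totals include them
  fr_rep <- dplyr::filter(w$fractions,
                          adm0_code %in% unique(w$stats$area_code))
  rep_crop <- harvested_area_report(ann$H, fr_rep, w$stats,
                                    concordance = w$concordance, by = "crop")
  # fodder is gridded but unreported; all reported crops reconcile exactly
  reported <- dplyr::filter(rep_crop, gaez_crop != "Fodder_crop")
  expect_equal(nrow(rep_crop), length(names(ann$H)))
  expect_lt(max(abs(reported$pct_difference)), 1e-6)
  # sorted by descending gridded total
  expect_true(!is.unsorted(rev(rep_crop$gridded_kha)))

  rep_country <- harvested_area_report(ann$H, w$fractions, w$stats,
                                       concordance = w$concordance,
                                       by = "country")
  expect_true(all(c(1001L, 98L) %in% rep_country$adm0_code))

  # under cap stress only the capped country under-reports; fodder is
  # gridded but never reported, so it is excluded from the comparison
  ws <- stress_world()
  anns <- stress_annual()
  h_reported <- anns$H[setdiff(names(anns$H), "Fodder_crop")]
  reps <- harvested_area_report(h_reported, ws$fractions, ws$stats,
                                concordance = ws$concordance, by = "country")
  short <- dplyr::filter(reps, statistic_kha > 0, pct_difference < -1e-6)
  expect_equal(short$adm0_code, 1001L)
})

test_that("percent differences format as in published tables", {
  expect_equal(format_pct_diff(c(-0.06, 0.1, 7.4, -27.2, 46)),
               c("-0.06", "+0.1", "+7", "-27", "+46"))
  expect_true(is.na(format_pct_diff(NA_real_)))
})
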