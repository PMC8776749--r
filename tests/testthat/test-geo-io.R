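test_that("file names follow the published templates exactly", {
  expect_equal(compose_filename("HarvArea", "Wheat", "Irrigated"),
               "GAEZAct2015_HarvArea_Wheat_Irrigated.tif")
  expect_equal(compose_filename("Yield", "Potato_&_Sweet_potato", "Mean"),
               "GAEZAct2015_Yield_Potato_&_Sweet_potato_Mean.tif")
  expect_equal(compose_filename("CropArea", "Rice", "Rainfed", subcrop = 2),
               "GAEZ_CropArea_Rice_2_Rainfed.nc")
  expect_error(compose_filename("HarvArea", "Wheat", "Foo"),
               "invalid management")
  expect_error(compose_filename("Area", "Wheat", "Irrigated"),
               "invalid variable")
  expect_error(compose_filename("CropArea", "Rice", "Total", subcrop = 1),
               "invalid monthly management")
  expect_error(compose_filename("CropArea", "Rice", "Rainfed", subcrop = 6),
               "subcrop in 1..5")
})

test_that("the canonical 5-arcmin global grid is 2160 x 4320", {
  expect_equal(global_grid_shape(1 / 12), c(2160, 4320))
  expect_equal(global_grid_shape(5), c(36, 72))
})

test_that("GeoTIFF layers round-trip with georeference and no-data mask", {
  withr::with_seed(9, {
    m <- matrix(runif(36 * 72) * 800, 36, 72)
    m[sample(length(m), 200)] <- NA
  })
  g <- crop_grid(m, west = -180, north = 90, cellsize = 5)
  f <- withr::local_tempfile(fileext = ".tif")
  write_raster(g, f)
  g2 <- read_raster(f)
  expect_identical(is.na(g2$values), is.na(g$values))
  # float32 storage: exact to one part in 2^23
  expect_lt(max(abs(g2$values - g$values), na.rm = TRUE),
            max(g$values, na.rm = TRUE) * 2^-22)
  expect_equal(c(g2$west, g2$north, g2$cellsize), c(-180, 90, 5))

  # no-data cells are stored as the published sentinel: parse the raw
  # float32 payload independently of read_raster
  con <- file(f, "rb")
  seek(con, 8)
  raw_vals <- readBin(con, "double", 36 * 72, size = 4, endian = "little")
  close(con)
  stored <- matrix(raw_vals, 36, 72, byrow = TRUE)
  expect_true(all(stored[is.na(g$values)] < -3.39e38))
  expect_true(all(stored[is.na(g$values)] > -3.41e38))
})

test_that("monthly cubes round-trip through compressed NetCDF", {
  withr::with_seed(10, a <- array(runif(36 * 72 * 12) * 50, c(36, 72, 12)))
  a[3, 5, ] <- NA
  geo <- tiny_grid(matrix(0, 36, 72))
  cube <- monthly_cube(a, geo, crop = "Rice", management = "Rainfed",
                       subcrop = 2L)
  f <- withr::local_tempfile(fileext = ".nc")
  write_monthly_netcdf(cube, f)
  cube2 <- read_monthly_netcdf(f)
  expect_equal(cube2$crop, "Rice")
  expect_equal(cube2$management, "Rainfed")
  expect_equal(cube2$subcrop, 2L)
  expect_identical(is.na(cube2$values), is.na(cube$values))
  expect_lt(max(abs(cube2$values - cube$values), na.rm = TRUE), 1e-4)
  expect_equal(c(cube2$west, cube2$north, cube2$cellsize), c(-180, 90, 5))

  # an all-zero crop still writes a full masked cube, not omitted layers
  z <- array(0, c(36, 72, 12)); z[1, 1, ] <- NA
  fz <- withr::local_tempfile(fileext = ".nc")
  write_monthly_netcdf(monthly_cube(z, geo, "Cassava", "Rainfed", 1L), fz)
  cz <- read_monthly_netcdf(fz)
  # deflate compression: a redundant cube shrinks far below the raw payload
  expect_lt(file.size(fz), 36 * 72 * 12 * 4 / 4)
  expect_equal(dim(cz$values), c(36, 72, 12))
  expect_true(all(cz$values == 0, na.rm = TRUE))
  expect_true(all(is.na(cz$values[1, 1, ])))

  bad <- array(0, c(4, 4, 11))
  expect_error(monthly_cube(bad, geo), "12")
})

test_that("annual layer sets are emitted under the naming template", {
  ann <- default_annual()
  dir <- withr::local_tempdir()
  files <- write_annual_layers(ann, dir)
  n_crops <- length(ann$H)
  expect_equal(nrow(files), n_crops * 3 * 2)
  expect_true(all(grepl(
    "^GAEZAct2015_(HarvArea|Production|Yield)_.+_(Irrigated|Rainfed)\\.tif$",
    basename(files$path))))
  expect_true(all(file.exists(files$path)))
  # values survive the trip at float32 precision
  back <- read_raster(files$path[files$variable == "HarvArea"][1])
  orig <- ann$H[[files$gaez_crop[1]]][["Irrigated"]]
  expect_identical(is.na(back$values), is.na(orig$values))
  expect_lt(max(abs(back$values - orig$values), na.rm = TRUE), 1e-3)
})

test_that("statistics, fraction and calendar tables round-trip", {
  w <- default_world()
  d <- withr::local_tempdir()
  write_faostat_csv(w$stats, file.path(d, "s.csv"))
  expect_equal(read_faostat_csv(file.path(d, "s.csv")), w$stats)
  write_cell_fractions(w$fractions, file.path(d, "f.tsv"))
  expect_equal(read_cell_fractions(file.path(d, "f.tsv")), w$fractions)
  write_calendar(w$calendar, file.path(d, "c.tsv"))
  expect_equal(read_calendar(file.path(d, "c.tsv")), w$calendar,
               tolerance = 1e-12)

  over <- tibble::tibble(cell_row = 1L, cell_col = 1L,
                         adm0_code = c(1L, 2L), fraction = c(0.7, 0.5))
  write_cell_fractions(over, file.path(d, "bad.tsv"))
  expect_error(read_cell_fractions(file.path(d, "bad.tsv")),
               "sum to more than 1")
})

test_that("a world bundle persists and reloads through the external formats", {
  w <- generate_world(world_config(seed = 55, crops = c("Wheat", "Rice"),
                                   n_countries = 2))
  d <- withr::local_tempdir()
  write_world_bundle(w, d)
  b <- read_world_bundle(d)
  expect_equal(names(b$h2010), c("Wheat", "Rice"))
  expect_identical(is.na(b$h2010$Wheat$Rainfed$values),
                   is.na(w$h2010$Wheat$Rainfed$values))
  expect_lt(max(abs(b$h2010$Wheat$Rainfed$values -
                      w$h2010$Wheat$Rainfed$values), na.rm = TRUE), 1e-3)
  expect_equal(b$stats, w$stats)
  expect_equal(b$fractions, w$fractions)
  expect_equal(b$splits, w$splits)
  # the reloaded bundle runs end to end
  rt <- build_ratio_table(b$stats, b$livestock, concordance = b$concordance,
                          registry = b$registry, splits = b$splits,
                          countries = unique(b$fractions$adm0_code))
  ann <- run_annual_update(b, ratios = rt)
  expect_lt(max(ann$conservation$rel_error, na.rm = TRUE), 1e-5)
})

test_that("the condensed-calendar adapter maps classes, cells and units", {
  grid <- tiny_grid(matrix(0, 36, 72))
  crop_names <- c("Wheat", "Rice", "Maize")
  df <- data.frame(
    lat = c(87.5, -87.5, 2.5),
    lon = c(-177.5, 177.5, -2.5),
    crop_class = c(1L, 5L, 3L),  # irrigated Wheat, rainfed Rice, irr. Maize
    subcrop = c(1L, 2L, 1L),
    area_ha = c(4000, 1500, 250),
    start_month = c(3L, 6L, 11L),
    end_month = c(7L, 10L, 2L)
  )
  cal <- adapt_condensed_calendar(df, grid, crop_names)
  expect_equal(cal$cell_row, c(1L, 36L, 18L))
  expect_equal(cal$cell_col, c(1L, 72L, 36L))
  expect_equal(cal$mirca_crop, c("Wheat", "Rice", "Maize"))
  expect_equal(cal$management, c("Irrigated", "Rainfed", "Irrigated"))
  expect_equal(cal$area, c(4, 1.5, 0.25))  # ha -> 1000 ha
  expect_error(adapt_condensed_calendar(transform(df, crop_class = 7L),
                                        grid, crop_names))
})

test_that("plot builders return ggplot objects", {
  w <- default_world()
  mo <- default_monthly()
  p1 <- plot_monthly_series(mo$months, crop = "Rice")
  expect_s3_class(p1, "ggplot")
  p2 <- ggplot2::autoplot(w$h2010$Wheat$Rainfed)
  expect_s3_class(p2, "ggplot")
  zs <- zonal_sum(w$h2010$Wheat$Rainfed, {
    z <- matrix(NA_integer_, 36, 72)
    fr <- dplyr::distinct(w$fractions, cell_row, cell_col, adm0_code)
    z[cbind(fr$cell_row, fr$cell_col)] <- fr$adm0_code
    z
  })
  p3 <- ggplot2::autoplot(compare_tables(zs, zs))
  expect_s3_class(p3, "ggplot")
})
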