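#' No-data sentinels of the published products
#' @name nodata
NULL

#' @rdname nodata
#' @export
NODATA_GEOTIFF <- -3.39999999999999996e+38

#' @rdname nodata
#' @export
NODATA_NETCDF <- -3.4e+38

#' Compose an output file name from the published templates
#'
#' Annual layers: `GAEZAct2015_{Variable}_{Cropname}_{Management}.tif` with
#' `Variable` in HarvArea/Production/Yield and `Management` in
#' Irrigated/Rainfed/Total/Mean. Monthly cubes:
#' `GAEZ_CropArea_{Cropname}_{subcrop}_{Management}.nc` with subcrop 1..5
#' and `Management` Irrigated/Rainfed.
#'
#' @param variable `"HarvArea"`, `"Production"`, `"Yield"`, or `"CropArea"`
#'   (monthly).
#' @param cropname GAEZ category name.
#' @param management Management string (see above).
#' @param subcrop Subcrop number 1..5, monthly only.
#' @return The composed file name.
#' @examples
#' compose_filename("HarvArea", "Wheat", "Irrigated")
#' compose_filename("CropArea", "Rice", "Rainfed", subcrop = 2)
#' @export
compose_filename <- function(variable, cropname, management, subcrop = NULL) {
  if (variable == "CropArea") {
    if (!management %in% c("Irrigated", "Rainfed"))
      stop("invalid monthly management: ", management)
    if (is.null(subcrop) || !subcrop %in% 1:5)
      stop("monthly file names need a subcrop in 1..5")
    sprintf("GAEZ_CropArea_%s_%d_%s.nc", cropname, as.integer(subcrop),
            management)
  } else {
    if (!variable %in% c("HarvArea", "Production", "Yield"))
      stop("invalid variable: ", variable)
    if (!management %in% c("Irrigated", "Rainfed", "Total", "Mean"))
      stop("invalid management: ", management)
    sprintf("GAEZAct2015_%s_%s_%s.tif", variable, cropname, management)
  }
}

#' Rows and columns of a global grid at a given cell size
#' @param cellsize Cell size in decimal degrees.
#' @return Integer vector `c(rows, cols)` covering -90..90 / -180..180.
#' @export
global_grid_shape <- function(cellsize = 1 / 12) {
  c(round(180 / cellsize), round(360 / cellsize))
}

# ---- GeoTIFF ----------------------------------------------------------------
# Single-sample float32 GeoTIFF, little-endian, uncompressed, striped.
# Written directly because no GDAL-backed raster package is available and
# plain image TIFF writers clamp samples to [0,1]. The layout carries the
# standard georeferencing tags (ModelPixelScale, ModelTiepoint,
# GeoKeyDirectory declaring geographic WGS84) and GDAL_NODATA.

#' Write and read float32 GeoTIFF layers
#'
#' Values are stored as 32-bit floats; `NA` cells become the published
#' no-data sentinel `-3.39999999999999996e+38`. Round-trips are exact at
#' float32 precision. `read_raster()` accepts only the layout this package
#' writes (uncompressed striped float32, one sample per pixel).
#'
#' @param layer A `crop_grid`.
#' @param path Output path.
#' @param nodata No-data sentinel written to file.
#' @return `write_raster()`: `path`, invisibly. `read_raster()`: a
#'   `crop_grid`.
#' @export
write_raster <- function(layer, path, nodata = NODATA_GEOTIFF) {
  v <- layer$values
  nr <- nrow(v); nc_ <- ncol(v)
  v[is.na(v)] <- nodata
  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")

  data_offset <- 8L
  data_bytes <- nr * nc_ * 4L
  # auxiliary values that do not fit in 4 bytes, placed after the image data
  scale_vals <- c(layer$cellsize, layer$cellsize, 0)
  tie_vals <- c(0, 0, 0, layer$west, layer$north, 0)
  geokeys <- as.integer(c(1, 1, 0, 3,
                          1024, 0, 1, 2,     # model type: geographic
                          1025, 0, 1, 1,     # raster type: pixel-is-area
                          2048, 0, 1, 4326)) # geographic CRS: WGS84
  nodata_str <- c(charToRaw(format(nodata, scientific = TRUE, digits = 17)),
                  as.raw(0))
  off_scale <- data_offset + data_bytes
  off_tie <- off_scale + 24L
  off_keys <- off_tie + 48L
  off_nodata <- off_keys + 32L
  ifd_offset <- off_nodata + length(nodata_str)
  if (ifd_offset %% 2L == 1L) ifd_offset <- ifd_offset + 1L

  wb(charToRaw("II"), 1L)
  wb(42L, 2L)
  wb(as.integer(ifd_offset), 4L)
  # image data, row-major, north-up
  wb(as.vector(t(v)), 4L)
  wb(scale_vals, 8L)
  wb(tie_vals, 8L)
  wb(geokeys, 2L)
  wb(nodata_str, 1L)
  if ((off_nodata + length(nodata_str)) %% 2L == 1L) wb(as.raw(0), 1L)

  entry <- function(tag, type, count, value_or_offset) {
    wb(as.integer(tag), 2L)
    wb(as.integer(type), 2L)
    wb(as.integer(count), 4L)
    if (type == 3L && count == 1L) {  # SHORT packed into the 4-byte slot
      wb(as.integer(value_or_offset), 2L); wb(0L, 2L)
    } else {
      wb(as.integer(value_or_offset), 4L)
    }
  }
  wb(14L, 2L)  # entry count
  entry(256, 4, 1, nc_)              # ImageWidth
  entry(257, 4, 1, nr)               # ImageLength
  entry(258, 3, 1, 32)               # BitsPerSample
  entry(259, 3, 1, 1)                # Compression: none
  entry(262, 3, 1, 1)                # Photometric: BlackIsZero
  entry(273, 4, 1, data_offset)      # StripOffsets
  entry(277, 3, 1, 1)                # SamplesPerPixel
  entry(278, 4, 1, nr)               # RowsPerStrip: single strip
  entry(279, 4, 1, data_bytes)       # StripByteCounts
  entry(339, 3, 1, 3)                # SampleFormat: IEEE float
  entry(33550, 12, 3, off_scale)     # ModelPixelScale
  entry(33922, 12, 6, off_tie)       # ModelTiepoint
  entry(34735, 3, 16, off_keys)      # GeoKeyDirectory
  entry(42113, 2, length(nodata_str), off_nodata)  # GDAL_NODATA
  wb(0L, 4L)  # no next IFD
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path, nodata = NODATA_GEOTIFF) {
  con <- file(path, "rb")
  on.exit(close(con))
  rb <- function(what, n, size) readBin(con, what, n = n, size = size,
                                        endian = "little")
  magic <- rawToChar(rb("raw", 2L, 1L))
  if (magic != "II") stop("unsupported TIFF byte order or not a TIFF: ", path)
  if (rb("integer", 1L, 2L) != 42L) stop("not a TIFF file: ", path)
  ifd_offset <- rb("integer", 1L, 4L)
  seek(con, ifd_offset)
  n_entries <- rb("integer", 1L, 2L)
  tags <- list()
  for (i in seq_len(n_entries)) {
    tag <- readBin(con, "integer", 1L, 2L, signed = FALSE, endian = "little")
    type <- rb("integer", 1L, 2L)
    count <- rb("integer", 1L, 4L)
    raw4 <- rb("raw", 4L, 1L)
    tags[[as.character(tag)]] <- list(type = type, count = count, raw4 = raw4)
  }
  val <- function(tag, default = NULL) {
    t <- tags[[as.character(tag)]]
    if (is.null(t)) return(default)
    sizes <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `12` = 8L)
    sz <- sizes[[as.character(t$type)]]
    total <- sz * t$count
    read_from <- function(con2) {
      switch(as.character(t$type),
             `2` = rawToChar(readBin(con2, "raw", t$count)),
             `3` = readBin(con2, "integer", t$count, 2L, endian = "little"),
             `4` = readBin(con2, "integer", t$count, 4L, endian = "little"),
             `12` = readBin(con2, "double", t$count, 8L, endian = "little"),
             readBin(con2, "raw", t$count))
    }
    if (total <= 4L) {
      rc <- rawConnection(t$raw4)
      on.exit(close(rc), add = TRUE)
      read_from(rc)
    } else {
      offset <- readBin(t$raw4, "integer", 1L, 4L, endian = "little")
      seek(con, offset)
      read_from(con)
    }
  }
  nc_ <- val(256); nr <- val(257)
  if (is.null(nc_) || is.null(nr)) stop("TIFF missing image dimensions")
  if (!identical(val(259, 1L), 1L)) stop("compressed TIFF not supported")
  if (!identical(val(258), 32L) || !identical(val(339, 1L), 3L))
    stop("only float32 sample format supported")
  offsets <- val(273)
  counts <- val(279)
  vals <- numeric(0)
  for (s in seq_along(offsets)) {
    seek(con, offsets[s])
    vals <- c(vals, rb("double", counts[s] / 4L, 4L))
  }
  m <- matrix(vals, nrow = nr, ncol = nc_, byrow = TRUE)
  m[m <= -3e38] <- NA_real_
  scale <- val(33550, c(1 / 12, 1 / 12, 0))
  tie <- val(33922, c(0, 0, 0, -180, 90, 0))
  keys <- val(34735)
  if (!is.null(keys)) {
    ks <- matrix(keys[-(1:4)], ncol = 4L, byrow = TRUE)
    crs <- ks[ks[, 1] == 2048, 4]
    if (length(crs) == 1L && crs != 4326L)
      warning("unexpected CRS code in GeoTIFF: ", crs)
  }
  crop_grid(m, west = tie[4], north = tie[5], cellsize = scale[1])
}

#' Write the full annual layer set as GeoTIFFs
#'
#' Emits one file per crop x variable x management following the published
#' naming template; the canonical 26-crop run with managements
#' Irrigated/Rainfed gives 156 files. `Total` (sum of managements) and
#' `Mean` yield (total production over total harvested area) can be added.
#'
#' @param result Output of [run_annual_update()].
#' @param dir Output directory (created if needed).
#' @param managements Managements to emit, default `c("Irrigated",
#'   "Rainfed")`.
#' @return Tibble of written files: `variable`, `gaez_crop`, `management`,
#'   `path`.
#' @export
write_annual_layers <- function(result, dir,
                                managements = c("Irrigated", "Rainfed")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  emit <- function(variable, crop, mgmt, layer) {
    f <- file.path(dir, compose_filename(variable, crop, mgmt))
    write_raster(layer, f)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      variable = variable, gaez_crop = crop, management = mgmt, path = f)
  }
  add <- function(a, b) {
    out <- a
    out$values <- ifelse(is.na(a$values) & is.na(b$values), NA_real_,
                         ifelse(is.na(a$values), 0, a$values) +
                           ifelse(is.na(b$values), 0, b$values))
    out
  }
  for (cr in names(result$H)) {
    for (m in managements) {
      if (m == "Total") {
        emit("HarvArea", cr, m, add(result$H[[cr]][["Irrigated"]],
                                    result$H[[cr]][["Rainfed"]]))
        emit("Production", cr, m, add(result$P[[cr]][["Irrigated"]],
                                      result$P[[cr]][["Rainfed"]]))
      } else if (m == "Mean") {
        ht <- add(result$H[[cr]][["Irrigated"]], result$H[[cr]][["Rainfed"]])
        pt <- add(result$P[[cr]][["Irrigated"]], result$P[[cr]][["Rainfed"]])
        emit("Yield", cr, m, compute_yield(pt, ht))
      } else {
        emit("HarvArea", cr, m, result$H[[cr]][[m]])
        emit("Production", cr, m, result$P[[cr]][[m]])
        emit("Yield", cr, m, result$Y[[cr]][[m]])
      }
    }
  }
  dplyr::bind_rows(rows)
}

# ---- NetCDF -----------------------------------------------------------------

#' Write and read a monthly cube as NetCDF
#'
#' Twelve-layer `CropArea` variable (units 1000 ha), float32 with internal
#' deflate compression (level 7), lon/lat coordinates, no-data `-3.4e+38`.
#'
#' @param cube A [monthly_cube()].
#' @param path Output path.
#' @param compression Deflate level, default 7.
#' @return `write_monthly_netcdf()`: `path`, invisibly;
#'   `read_monthly_netcdf()`: a `monthly_cube`.
#' @export
write_monthly_netcdf <- function(cube, path, compression = 7) {
  d <- dim(cube$values)
  if (length(d) != 3L || d[3] != 12L) stop("cube must have 12 monthly layers")
  lon <- cube$west + (seq_len(d[2]) - 0.5) * cube$cellsize
  lat <- cube$north - (seq_len(d[1]) - 0.5) * cube$cellsize
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", lat)
  dim_mon <- ncdf4::ncdim_def("month", "month", 1:12)
  var <- ncdf4::ncvar_def("CropArea", "1000 ha",
                          list(dim_lon, dim_lat, dim_mon),
                          missval = NODATA_NETCDF, prec = "float",
                          compression = compression)
  nc <- ncdf4::nc_create(path, var, force_v4 = TRUE)
  on.exit(ncdf4::nc_close(nc))
  # nc layout is lon x lat x month; internal layout is row(lat) x col(lon)
  a <- aperm(cube$values, c(2, 1, 3))
  ncdf4::ncvar_put(nc, var, a)
  ncdf4::ncatt_put(nc, 0, "crs", "+proj=longlat +datum=WGS84")
  if (!is.na(cube$crop)) ncdf4::ncatt_put(nc, 0, "crop", cube$crop)
  if (!is.na(cube$management))
    ncdf4::ncatt_put(nc, 0, "management", cube$management)
  if (!is.na(cube$subcrop))
    ncdf4::ncatt_put(nc, 0, "subcrop", as.integer(cube$subcrop))
  invisible(path)
}

#' @rdname write_monthly_netcdf
#' @export
read_monthly_netcdf <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  a <- ncdf4::ncvar_get(nc, "CropArea", collapse_degen = FALSE)
  lon <- ncdf4::ncvar_get(nc, "lon")
  lat <- ncdf4::ncvar_get(nc, "lat")
  cellsize <- abs(lon[2] - lon[1])
  att <- function(name) {
    a <- ncdf4::ncatt_get(nc, 0, name)
    if (a$hasatt) a$value else NA
  }
  vals <- aperm(a, c(2, 1, 3))
  geo <- list(west = lon[1] - cellsize / 2, north = lat[1] + cellsize / 2,
              cellsize = cellsize)
  monthly_cube(vals, geo, crop = as.character(att("crop")),
               management = as.character(att("management")),
               subcrop = as.integer(att("subcrop")))
}

#' Write all monthly cubes of a run
#'
#' One NetCDF per (crop, subcrop, management) following the published
#' template.
#'
#' @param monthly Output of [run_monthly()].
#' @param dir Output directory.
#' @return Tibble of written files.
#' @export
write_monthly_layers <- function(monthly, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (cr in names(monthly$cubes)) {
    for (m in names(monthly$cubes[[cr]])) {
      for (n in seq_along(monthly$cubes[[cr]][[m]])) {
        cube <- monthly$cubes[[cr]][[m]][[n]]
        if (is.null(cube)) next
        f <- file.path(dir, compose_filename("CropArea", cr, m, subcrop = n))
        write_monthly_netcdf(cube, f)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gaez_crop = cr, management = m, subcrop = n, path = f)
      }
    }
  }
  dplyr::bind_rows(rows)
}
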