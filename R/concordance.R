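#' Crop concordance tables
#'
#' The pipeline harmonises three crop lists: the FAOSTAT production-domain
#' crops (about 160 codes), the 26 GAEZ crop categories used for all gridded
#' outputs, and the MIRCA2000 crop list used for monthly calendars. Both
#' concordances ship as editable plain-text tables so miniature synthetic
#' worlds can run on reduced crop sets; the packaged files reproduce the
#' canonical harmonisation.
#'
#' @param path Path to a delimited concordance file. Defaults to the packaged
#'   canonical table.
#' @return `read_crop_concordance()`: a tibble with columns `faostat_code`,
#'   `faostat_name`, `gaez_crop`, `no_longer_reported` (fodder crops are
#'   flagged: FAOSTAT stopped reporting their harvested area and production).
#' @examples
#' conc <- read_crop_concordance()
#' dplyr::count(conc, gaez_crop)
#' @export
read_crop_concordance <- function(path = NULL) {
  path <- path %||% system.file("extdata", "faostat_gaez_concordance.tsv",
                                package = "gaezplus", mustWork = TRUE)
  tibble::as_tibble(readr::read_tsv(path, col_types = readr::cols(
    faostat_code = readr::col_integer(),
    faostat_name = readr::col_character(),
    gaez_crop = readr::col_character(),
    no_longer_reported = readr::col_logical()
  )))
}

#' @rdname read_crop_concordance
#' @return `read_mirca_matches()`: a tibble with columns `gaez_crop`,
#'   `mirca_crops` (list-column of 1-2 MIRCA crop names), `one_to_one`,
#'   `removal_order` (1 = first crop removed when a cell-month overflows,
#'   staples carry large numbers).
#' @export
read_mirca_matches <- function(path = NULL) {
  path <- path %||% system.file("extdata", "gaez_mirca_matches.tsv",
                                package = "gaezplus", mustWork = TRUE)
  tibble::as_tibble(readr::read_tsv(path, col_types = readr::cols(
    gaez_crop = readr::col_character(),
    mirca_crops = readr::col_character(),
    one_to_one = readr::col_logical(),
    removal_order = readr::col_integer()
  ))) |>
    dplyr::mutate(mirca_crops = strsplit(.data$mirca_crops, ";", fixed = TRUE))
}

#' @rdname read_crop_concordance
#' @return `read_special_regions()`: a tibble with `adm0_code`, `name`,
#'   `kind` (`"no_data"`: 49 small regions and islands with no FAOSTAT crop
#'   data; `"disputed"`: 9 disputed areas). Both kinds are held at a change
#'   ratio of 1.0.
#' @export
read_special_regions <- function(path = NULL) {
  path <- path %||% system.file("extdata", "special_regions.tsv",
                                package = "gaezplus", mustWork = TRUE)
  tibble::as_tibble(readr::read_tsv(path, col_types = readr::cols(
    adm0_code = readr::col_integer(),
    name = readr::col_character(),
    kind = readr::col_character()
  )))
}

#' The 26 GAEZ crop category names
#' @return Character vector of the canonical category names.
#' @export
gaez_crop_names <- function() {
  c("Wheat", "Rice", "Maize", "Sorghum", "Millet", "Barley", "Other_cereals",
    "Potato_&_Sweet_potato", "Cassava", "Yams_and_other_roots", "Sugarbeet",
    "Sugarcane", "Pulses", "Soybean", "Rapeseed", "Sunflower", "Groundnut",
    "Oil_palm_fruit", "Olives", "Cotton", "Tobacco", "Banana", "Stimulants",
    "Vegetables", "Crops_NES", "Fodder_crop")
}

#' Normalise a crop name for comparison
#'
#' Published materials mix variants like "Potato & Sweet potato" and
#' "Potato_&_Sweet_potato"; comparison folds case and maps spaces and
#' ampersands to underscores (runs collapsed).
#' @param x Character vector of crop names.
#' @return Normalised character vector.
#' @export
normalize_crop_name <- function(x) {
  x <- gsub("[ &]+", "_", x)
  x <- gsub("_+", "_", x)
  tolower(x)
}

#' Look up the GAEZ category of a FAOSTAT crop code
#'
#' @param faostat_code Integer vector of FAOSTAT production-domain codes.
#' @param concordance Concordance tibble from [read_crop_concordance()].
#' @return Character vector of GAEZ category names.
#' @examples
#' lookup_gaez_category(15) # "Wheat"
#' @export
lookup_gaez_category <- function(faostat_code,
                                 concordance = read_crop_concordance()) {
  idx <- match(faostat_code, concordance$faostat_code)
  if (anyNA(idx)) {
    stop("unmapped crop code: ",
         paste(faostat_code[is.na(idx)], collapse = ", "))
  }
  concordance$gaez_crop[idx]
}

#' Look up the MIRCA2000 match for a GAEZ crop
#'
#' @param gaez_crop A single GAEZ category name (name variants are folded via
#'   [normalize_crop_name()]).
#' @param matches Match tibble from [read_mirca_matches()].
#' @return A one-row tibble: `gaez_crop`, `mirca_crops` (list-column),
#'   `one_to_one`, `removal_order`.
#' @examples
#' lookup_mirca_match("Rice")$removal_order # 19
#' @export
lookup_mirca_match <- function(gaez_crop, matches = read_mirca_matches()) {
  stopifnot(length(gaez_crop) == 1L)
  idx <- match(normalize_crop_name(gaez_crop),
               normalize_crop_name(matches$gaez_crop))
  if (is.na(idx)) stop("unknown GAEZ crop: ", gaez_crop)
  matches[idx, ]
}

#' Validate concordance tables
#'
#' Report-only structural checks: duplicate FAOSTAT codes, GAEZ categories
#' missing from either table, unknown categories, removal orders outside
#' 1..21, and multi-match entries.
#'
#' @param concordance Tibble from [read_crop_concordance()].
#' @param matches Tibble from [read_mirca_matches()].
#' @param crop_names Reference set of category names (defaults to the 26
#'   canonical names).
#' @return A tibble with columns `check`, `item`; zero rows iff both tables
#'   are well-formed.
#' @export
validate_concordance <- function(concordance = read_crop_concordance(),
                                 matches = read_mirca_matches(),
                                 crop_names = gaez_crop_names()) {
  problems <- list()
  note <- function(check, item) {
    problems[[length(problems) + 1L]] <<- tibble::tibble(check = check,
                                                         item = as.character(item))
  }

  dup <- concordance$faostat_code[duplicated(concordance$faostat_code)]
  for (d in unique(dup)) note("duplicate_faostat_code", d)

  ref <- normalize_crop_name(crop_names)
  for (nm in crop_names[!ref %in% normalize_crop_name(concordance$gaez_crop)])
    note("gaez_crop_missing_from_concordance", nm)
  for (nm in crop_names[!ref %in% normalize_crop_name(matches$gaez_crop)])
    note("gaez_crop_missing_from_matches", nm)
  for (nm in unique(concordance$gaez_crop[
    !normalize_crop_name(concordance$gaez_crop) %in% ref]))
    note("unknown_gaez_crop_in_concordance", nm)
  for (nm in unique(matches$gaez_crop[
    !normalize_crop_name(matches$gaez_crop) %in% ref]))
    note("unknown_gaez_crop_in_matches", nm)

  bad_ord <- matches$gaez_crop[is.na(matches$removal_order) |
                                 matches$removal_order < 1L |
                                 matches$removal_order > 21L]
  for (nm in bad_ord) note("removal_order_out_of_range", nm)

  n_mirca <- lengths(matches$mirca_crops)
  for (nm in matches$gaez_crop[n_mirca < 1L]) note("no_mirca_crop", nm)

  if (length(problems) == 0L) {
    tibble::tibble(check = character(), item = character())
  } else {
    dplyr::bind_rows(problems)
  }
}

#' Write concordance tables back to delimited text
#'
#' Round-trip companions to the readers; used by the synthetic-world
#' generator to emit reduced crop sets in the exact on-disk layout.
#' @param concordance,matches Tibbles in reader layout.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_crop_concordance <- function(concordance, path) {
  readr::write_tsv(concordance, path)
  invisible(path)
}

#' @rdname write_crop_concordance
#' @export
write_mirca_matches <- function(matches, path) {
  out <- dplyr::mutate(
    matches,
    mirca_crops = purrr::map_chr(.data$mirca_crops, paste, collapse = ";")
  )
  readr::write_tsv(out, path)
  invisible(path)
}
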