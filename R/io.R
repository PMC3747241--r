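# File interfaces: CSV sample/meteorology tables, GeoJSON region polygons,
# optional single-band TIFF scenes, and the output bundle of a run.

apply_col_map <- function(df, col_map) {
  if (is.null(col_map)) return(df)
  for (std in names(col_map)) {
    if (!col_map[[std]] %in% names(df)) {
      abort(sprintf("column '%s' (mapped to '%s') not found in file.",
                    col_map[[std]], std))
    }
  }
  rename(df, !!!setNames(unlist(col_map), names(col_map)))
}

#' Read a water-sample CSV
#'
#' Expects ISO-8601 dates and empty fields for missing values; column names
#' can be remapped with `col_map` (a named character vector
#' `standard_name = "file_column"`).
#'
#' @param path CSV path.
#' @param col_map Optional column remapping.
#' @param validate Run [validate_water_samples()] after reading.
#' @return A tibble of water samples.
#' @export
read_water_samples <- function(path, col_map = NULL, validate = TRUE) {
  df <- readr::read_csv(path, show_col_types = FALSE) %>%
    apply_col_map(col_map)
  if ("date" %in% names(df)) df$date <- as.Date(df$date)
  if (validate) validate_water_samples(df)
  df
}

#' Read an hourly meteorology CSV
#'
#' @inheritParams read_water_samples
#' @return A tibble with `timestamp`, `station_id`, `wind_m_s`,
#'   `sensor_height_m` and any further columns present.
#' @export
read_meteorology <- function(path, col_map = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE) %>%
    apply_col_map(col_map)
  need <- c("timestamp", "station_id", "wind_m_s", "sensor_height_m")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste("meteorology file missing columns:", paste(miss, collapse = ", ")))
  }
  df
}

#' Read region polygons from a GeoJSON file
#'
#' Supports a FeatureCollection of (simple, unholed) Polygon features; the
#' region id is taken from the `region_id` (or `id`, or `name`) property.
#'
#' @param path GeoJSON path.
#' @return A named list of data frames with `x`, `y` vertex columns.
#' @export
read_region_polygons <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    abort("read_region_polygons(): expected a GeoJSON FeatureCollection.")
  }
  polys <- purrr::map(gj$features, function(ft) {
    if (!identical(ft$geometry$type, "Polygon")) {
      abort("read_region_polygons(): only Polygon geometries are supported.")
    }
    ring <- ft$geometry$coordinates[[1]]
    coords <- do.call(rbind, purrr::map(ring, ~ as.numeric(unlist(.x))))
    data.frame(x = coords[, 1], y = coords[, 2])
  })
  ids <- purrr::map_chr(gj$features, function(ft) {
    as.character(ft$properties$region_id %||% ft$properties$id %||%
                   ft$properties$name %||% NA_character_)
  })
  if (anyNA(ids)) abort("read_region_polygons(): features need a region_id/id/name property.")
  setNames(polys, ids)
}

#' Read a single-band reflectance raster from a (Geo)TIFF
#'
#' Thin wrapper over the `tiff` package for single-band surface-reflectance
#' rasters scaled to `[0, 1]`; the georeferencing (pixel size, origin) is
#' passed explicitly because plain TIFF readers do not carry it.
#'
#' @param path TIFF path.
#' @param pixel_size_m Ground resolution, m.
#' @param date Acquisition date.
#' @param origin Map coordinates of the grid corner.
#' @param nodata Reflectance value to be treated as nodata, if any.
#' @return A [reflectance_scene()].
#' @export
read_scene_tiff <- function(path, pixel_size_m, date = NULL, origin = c(0, 0),
                            nodata = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("read_scene_tiff() needs the 'tiff' package.")
  }
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  if (!is.null(nodata)) img[img == nodata] <- NA_real_
  reflectance_scene(img, pixel_size_m, date = date, origin = origin)
}

#' Write the output bundle of a run
#'
#' Writes the per-site and per-region tables as CSV plus a JSON metadata
#' sidecar (package version, configuration hash, parameterization) to a
#' directory.  Reruns with identical inputs produce byte-identical files.
#'
#' @param run A `wetflux_run`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_run_outputs <- function(run, dir) {
  stopifnot(inherits(run, "wetflux_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("speciated", "flux_daily", "site_annual", "pco2_stats",
              "flux_stats", "region_daily", "region_annual", "annual_table",
              "sensitivity", "budget")
  paths <- character()
  for (tb in tables) {
    if (is.null(run[[tb]])) next
    p <- file.path(dir, paste0(tb, ".csv"))
    readr::write_csv(run[[tb]], p)
    paths <- c(paths, p)
  }
  meta_path <- file.path(dir, "run_metadata.json")
  jsonlite::write_json(run$meta, meta_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, meta_path))
}
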