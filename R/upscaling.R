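# Remote-sensing water extent and regional up-scaling of areal fluxes.
#
# Water is mapped by a near-infrared reflectance threshold on radiometrically
# normalized scenes; per-region water areas (pixel counting inside region
# polygons) are interpolated to daily series, and daily carbon transport is
# the wet-site mean areal flux times the water area of the region.

#' Construct a single-band reflectance scene
#'
#' A minimal in-memory raster: a matrix of near-infrared surface reflectance
#' in `[0, 1]` (`NA` = nodata), a ground pixel size and the map coordinates of
#' the grid origin.  Pixel centers are at
#' `x = x0 + (col - 0.5) * pixel_size`, `y = y0 + (row - 0.5) * pixel_size`.
#'
#' @param nir Numeric matrix of NIR reflectance.
#' @param pixel_size_m Ground resolution, m (e.g. 30 for Landsat TM, 22 for
#'   DEIMOS-1).
#' @param date Acquisition date.
#' @param origin Map coordinates `c(x0, y0)` of the grid corner.
#' @return An object of class `reflectance_scene`.
#' @export
reflectance_scene <- function(nir, pixel_size_m, date = NULL, origin = c(0, 0)) {
  stopifnot(is.matrix(nir), pixel_size_m > 0)
  rng <- range(nir, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) abort("reflectance_scene(): reflectance must lie in [0, 1].")
  structure(
    list(nir = nir, pixel_size_m = pixel_size_m, date = date, origin = origin,
         normalization = NULL),
    class = "reflectance_scene"
  )
}

#' @export
print.reflectance_scene <- function(x, ...) {
  cat(sprintf(
    "<reflectance_scene %s: %d x %d px @ %g m, %d nodata>\n",
    if (is.null(x$date)) "(undated)" else format(x$date),
    nrow(x$nir), ncol(x$nir), x$pixel_size_m, sum(is.na(x$nir))
  ))
  invisible(x)
}

scene_cell_index <- function(scene, x, y) {
  col <- pmin(pmax(ceiling((x - scene$origin[1]) / scene$pixel_size_m), 1), ncol(scene$nir))
  row <- pmin(pmax(ceiling((y - scene$origin[2]) / scene$pixel_size_m), 1), nrow(scene$nir))
  cbind(row, col)
}

scene_pixel_centers <- function(scene, idx = NULL) {
  nr <- nrow(scene$nir)
  if (is.null(idx)) idx <- seq_along(scene$nir)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  cbind(
    x = scene$origin[1] + (col - 0.5) * scene$pixel_size_m,
    y = scene$origin[2] + (row - 0.5) * scene$pixel_size_m
  )
}

#' Relative radiometric normalization against a reference scene
#'
#' Fits a major-axis line to the (scene, reference) reflectance pairs of the
#' pseudo-invariant features — slope \eqn{\mathrm{sign(cov)}
#' \sqrt{\mathrm{var_{ref}}/\mathrm{var_{scene}}}}, intercept through the
#' means, the symmetric fit appropriate when both axes carry error — and
#' applies it to the whole scene, clipping to `[0, 1]`.
#'
#' @param scene,reference `reflectance_scene` objects.
#' @param pif_pixels Pseudo-invariant features valid in both scenes (>= 3
#'   required): either a two-column matrix of (row, col) indices (scenes must
#'   then share one grid) or a data frame with map coordinates `x`, `y`,
#'   which are resolved to pixels per scene and therefore work across
#'   resolutions.
#' @return The normalized scene; the fitted `slope` and `intercept` are
#'   stored in its `normalization` field.
#' @export
normalize_scene <- function(scene, reference, pif_pixels) {
  if (is.data.frame(pif_pixels) && all(c("x", "y") %in% names(pif_pixels))) {
    x <- scene$nir[scene_cell_index(scene, pif_pixels$x, pif_pixels$y)]
    y <- reference$nir[scene_cell_index(reference, pif_pixels$x, pif_pixels$y)]
  } else {
    pif_pixels <- as.matrix(pif_pixels)
    x <- scene$nir[pif_pixels]
    y <- reference$nir[pif_pixels]
  }
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) abort("normalize_scene(): need >= 3 PIF pixels valid in both scenes.")
  x <- x[ok]; y <- y[ok]
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 || vy == 0) abort("normalize_scene(): zero variance in the PIF set.")
  slope <- sign(stats::cov(x, y)) * sqrt(vy / vx)
  intercept <- mean(y) - slope * mean(x)
  out <- scene
  out$nir <- pmin(pmax(intercept + slope * scene$nir, 0), 1)
  out$normalization <- list(slope = slope, intercept = intercept, n_pif = sum(ok))
  out
}

#' Classify water pixels by NIR threshold
#'
#' A pixel is water iff its near-infrared reflectance is strictly less than
#' the threshold (default 0.2); nodata pixels belong to neither class.
#'
#' @param scene A `reflectance_scene`.
#' @param threshold NIR reflectance cutoff in (0, 1).
#' @return A logical matrix (`NA` where nodata).
#' @export
classify_water <- function(scene, threshold = 0.2) {
  stopifnot(threshold > 0, threshold < 1)
  scene$nir < threshold
}

#' Water surface area of a region
#'
#' Counts the water pixels whose centers fall inside the region polygon and
#' multiplies by the pixel area.
#'
#' @param mask Logical water mask from [classify_water()].
#' @param scene The scene the mask came from (for geometry).
#' @param polygon Data frame or matrix of polygon vertices (`x`, `y`), in the
#'   scene's map coordinates.
#' @return Area, km2 (0 with a warning when the polygon misses the raster).
#' @examples
#' # 100 water pixels at 30 m -> 100 * 900 / 1e6 = 0.09 km2
#' @export
region_water_area <- function(mask, scene, polygon) {
  polygon <- as.matrix(polygon[, c(1, 2)])
  ext <- c(scene$origin[1], scene$origin[1] + ncol(mask) * scene$pixel_size_m,
           scene$origin[2], scene$origin[2] + nrow(mask) * scene$pixel_size_m)
  if (max(polygon[, 1]) < ext[1] || min(polygon[, 1]) > ext[2] ||
      max(polygon[, 2]) < ext[3] || min(polygon[, 2]) > ext[4]) {
    warn("region_water_area(): polygon does not intersect the raster; area = 0.")
    return(0)
  }
  water_idx <- which(!is.na(mask) & mask)
  if (length(water_idx) == 0) return(0)
  centers <- scene_pixel_centers(scene, water_idx)
  # bounding-box prefilter keeps the exact point-in-polygon test small
  bb <- centers[, 1] >= min(polygon[, 1]) & centers[, 1] <= max(polygon[, 1]) &
    centers[, 2] >= min(polygon[, 2]) & centers[, 2] <= max(polygon[, 2])
  if (!any(bb)) return(0)
  inside <- mgcv::in.out(polygon, centers[bb, , drop = FALSE])
  sum(inside) * scene$pixel_size_m^2 / 1e6
}

#' Daily water-area series from scene-date areas
#'
#' Linear interpolation of per-scene region areas onto the daily calendar,
#' exact at scene dates; a single scene yields a constant series with a
#' warning.  Shares the interpolation rule of [interpolate_daily()].
#'
#' @param areas Data frame with `date`, `area_km2` and optionally
#'   `region_id`.
#' @return A tibble with (`region_id`,) `date`, `area_km2`, daily.
#' @export
interpolate_area_daily <- function(areas) {
  stopifnot(all(c("date", "area_km2") %in% names(areas)))
  if (!"region_id" %in% names(areas)) areas$region_id <- "region"
  areas %>%
    as_tibble() %>%
    group_by(.data$region_id) %>%
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$date)
      if (nrow(df) == 1) {
        warn(sprintf(
          "interpolate_area_daily(): single scene for region %s; constant series.",
          key$region_id
        ))
        return(tibble(date = df$date, area_km2 = df$area_km2))
      }
      days <- seq(min(df$date), max(df$date), by = "day")
      tibble(date = days,
             area_km2 = interp_daily_series(df$date, df$area_km2, days))
    }) %>%
    ungroup()
}

#' Daily regional carbon transport
#'
#' Averages the daily areal fluxes of the region's wet member sites (sites
#' dry that day simply drop out of the mean) and multiplies by the region's
#' water surface area, converting moles of CO2 to grams of carbon with the
#' molar mass 12.011 g mol-1:
#' transport (g C d-1) = mean flux (mmol m-2 d-1) x 1e-3 mol/mmol x
#' area (km2) x 1e6 m2/km2 x 12.011 g/mol.
#'
#' Days on which the region still has water area but no wet member site are
#' reported as zero transport with a logged inconsistency count.
#'
#' @param flux_records Daily flux records ([daily_fluxes()]) for the member
#'   sites of all regions.
#' @param region_sites Data frame mapping `region_id` to `site_id`.
#' @param area_daily Daily water areas with `region_id`, `date`, `area_km2`.
#' @return A tibble with `region_id`, `date`, `mean_flux_mmol_m2_d`,
#'   `n_sites_wet`, `area_km2`, `transport_g_c_d`.
#' @export
regional_daily_transport <- function(flux_records, region_sites, area_daily) {
  stopifnot(all(c("region_id", "site_id") %in% names(region_sites)),
            all(c("region_id", "date", "area_km2") %in% names(area_daily)))
  site_means <- flux_records %>%
    inner_join(as_tibble(region_sites), by = "site_id") %>%
    group_by(.data$region_id, .data$date) %>%
    summarise(mean_flux_mmol_m2_d = mean(.data$flux_mmol_m2_d),
              n_sites_wet = dplyr::n(), .groups = "drop")
  out <- area_daily %>%
    as_tibble() %>%
    left_join(site_means, by = c("region_id", "date")) %>%
    mutate(
      n_sites_wet = ifelse(is.na(.data$n_sites_wet), 0L, .data$n_sites_wet),
      transport_g_c_d = ifelse(
        .data$n_sites_wet == 0, 0,
        .data$mean_flux_mmol_m2_d * 1e-3 * .data$area_km2 * 1e6 * 12.011
      )
    )
  n_bad <- sum(out$n_sites_wet == 0 & out$area_km2 > 0)
  if (n_bad > 0) {
    inform(sprintf(
      "regional_daily_transport(): %d day(s) with water area but no wet site; transport set to 0.",
      n_bad
    ))
  }
  out
}

#' Annual carbon transport of a region
#'
#' @param transport_g_c_d Daily transports, g C d-1 (at most 366 values per
#'   region; negative days propagate).
#' @return Annual transport, Gg C y-1 (sum of grams / 1e9).
#' @examples
#' annual_transport(rep(1e5, 365))   # 0.0365
#' @export
annual_transport <- function(transport_g_c_d) {
  if (length(transport_g_c_d) > 366) {
    abort("annual_transport(): more than 366 daily values.")
  }
  sum(transport_g_c_d, na.rm = TRUE) / 1e9
}

#' Compare annual aquatic CO2 transport with potential net primary production
#'
#' Converts an areal NPP (mol C m-2 y-1) over a region area to Gg C y-1 and
#' forms its ratio to the annual air-water carbon transport.  The ratio is
#' undefined (flagged `NA`) when transport is not positive.
#'
#' @param npp_mol_m2_y Areal potential NPP, mol C m-2 y-1.
#' @param region_area_km2 Region area, km2.
#' @param total_transport_gg Annual air-water transport, Gg C y-1 (any sign).
#' @return A tibble with `npp_gg_c_y`, `ratio` and `ratio_defined`.
#' @examples
#' npp_comparison(27, 231, 13.1)   # npp ~75 Gg C y-1, ratio ~5.7
#' @export
npp_comparison <- function(npp_mol_m2_y, region_area_km2, total_transport_gg = NA) {
  stopifnot(npp_mol_m2_y > 0, region_area_km2 > 0)
  npp_gg <- npp_mol_m2_y * 12.011 * region_area_km2 * 1e6 / 1e9
  defined <- is.finite(total_transport_gg) && total_transport_gg > 0
  tibble(
    npp_gg_c_y = npp_gg,
    ratio = if (defined) npp_gg / total_transport_gg else NA_real_,
    ratio_defined = defined
  )
}
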