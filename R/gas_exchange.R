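# Gas-transfer velocity and areal air-water CO2 flux.
#
# F = kt * K0 * (pCO2_water - pCO2_air), positive = efflux to the atmosphere.
# kt comes from a wind-driven k600 parameterization rescaled to the in-situ
# Schmidt number; all parameterization coefficients are configuration data,
# not code (default_k600_params()).

#' Adjust wind speed to the 10 m reference height
#'
#' Neutral-stability logarithmic profile with a constant drag coefficient.
#' The roughness length follows from the drag coefficient via
#' \eqn{C_d = (\kappa / \ln(10/z_0))^2} with von Karman's constant 0.4, so
#' the default \eqn{C_d = 1.3\times10^{-3}} gives \eqn{z_0 = 1.52\times10^{-4}} m.
#' Daily-mean winds do not support atmospheric-stability corrections, so none
#' are attempted.
#'
#' @param u_z Wind speed at sensor height, m s-1.
#' @param sensor_height_m Sensor height above the surface, m (0 < z <= 30).
#' @param drag_coefficient Neutral drag coefficient at 10 m.
#' @return Wind speed at 10 m, m s-1.  Equal to `u_z` when the sensor is at 10 m.
#' @examples
#' wind_to_10m(3, 10)   # 3
#' wind_to_10m(3, 2)    # > 3
#' @export
wind_to_10m <- function(u_z, sensor_height_m, drag_coefficient = 1.3e-3) {
  if (any(sensor_height_m <= 0) || any(sensor_height_m > 30)) {
    abort("wind_to_10m(): sensor_height_m must be in (0, 30].")
  }
  stopifnot(all(u_z >= 0))
  z0 <- 10 / exp(0.4 / sqrt(drag_coefficient))
  u_z * log(10 / z0) / log(sensor_height_m / z0)
}

#' Spatially averaged daily wind series
#'
#' Collapses several station series to one regional daily series: each station
#' is first time-averaged within the day, then stations are averaged
#' arithmetically.  Days on which a station has no data are averaged over the
#' remaining stations; days with no station data at all propagate as `NA`
#' (never zero-filled).
#'
#' @param station_winds A data frame with columns `date`, `station_id` and
#'   `u10_m_s` (one row per observation; sub-daily rows are averaged).
#' @return A tibble with `date` and `u10_m_s`.
#' @export
spatial_wind_ensemble <- function(station_winds) {
  stopifnot(all(c("date", "station_id", "u10_m_s") %in% names(station_winds)))
  station_winds %>%
    group_by(.data$date, .data$station_id) %>%
    summarise(u10_m_s = mean(.data$u10_m_s, na.rm = TRUE), .groups = "drop") %>%
    mutate(u10_m_s = ifelse(is.nan(.data$u10_m_s), NA_real_, .data$u10_m_s)) %>%
    group_by(.data$date) %>%
    summarise(u10_m_s = if (all(is.na(.data$u10_m_s))) NA_real_ else
      mean(.data$u10_m_s, na.rm = TRUE), .groups = "drop") %>%
    arrange(.data$date)
}

#' Schmidt number of CO2 in natural waters
#'
#' Fourth-order polynomials in temperature for the freshwater and seawater
#' (S = 35) endmembers, interpolated linearly in salinity.  The freshwater
#' polynomial gives Sc very near 600 at 20 C, the premise of the k600
#' normalization.
#'
#' @param temp_c Water temperature, degrees C (valid 0-40).
#' @param salinity Practical salinity.
#' @param coef_fresh,coef_sea Polynomial coefficients (intercept, then
#'   ascending powers of T with alternating sign convention
#'   `a - b t + c t^2 - d t^3 + e t^4`).
#' @return Dimensionless Schmidt number, strictly decreasing in temperature.
#' @examples
#' schmidt_number(20, 0)   # ~600
#' @export
schmidt_number <- function(temp_c, salinity = 0,
                           coef_fresh = c(1923.6, 125.06, 4.3773, 0.085681, 0.00070284),
                           coef_sea = c(2116.8, 136.25, 4.7353, 0.092307, 0.0007555)) {
  stopifnot(all(temp_c >= 0 & temp_c <= 40))
  poly4 <- function(cf, t) cf[1] - cf[2] * t + cf[3] * t^2 - cf[4] * t^3 + cf[5] * t^4
  sc0 <- poly4(coef_fresh, temp_c)
  sc35 <- poly4(coef_sea, temp_c)
  w <- pmin(pmax(salinity / 35, 0), 50 / 35)   # linear in S, extrapolated above 35
  sc0 + (sc35 - sc0) * w
}

#' Default k600 parameterization coefficients
#'
#' All three wind relationships share the form
#' \eqn{k_{600} = a + b\,U_{10}^{c}} (cm h-1, U10 in m s-1):
#'
#' * `lake` — Cole & Caraco (1998), whole-lake SF6: a = 2.07, b = 0.215,
#'   c = 1.7.  The positive intercept is the calm-water floor.
#' * `small_water_body` — Crusius & Wanninkhof (2003) low-wind power fit:
#'   a = 0.168, b = 0.228, c = 2.2.
#' * `ocean` — Wanninkhof (1992) quadratic, 0.31 U10^2 at Sc 660, rescaled to
#'   the Sc 600 convention used here (factor (660/600)^0.5): b = 0.3251, c = 2.
#'
#' @return A tibble with columns `parameterization_id`, `a`, `b`, `c` and
#'   `reference`.
#' @export
default_k600_params <- function() {
  tibble(
    parameterization_id = c("lake", "small_water_body", "ocean"),
    a = c(2.07, 0.168, 0),
    b = c(0.215, 0.228, 0.31 * sqrt(660 / 600)),
    c = c(1.7, 2.2, 2),
    reference = c("Cole & Caraco 1998", "Crusius & Wanninkhof 2003",
                  "Wanninkhof 1992 (rescaled Sc 660 -> 600)")
  )
}

#' Wind-driven gas-transfer velocity normalized to Sc = 600
#'
#' @param u10 Daily-mean wind speed at 10 m, m s-1.
#' @param parameterization One of the ids in `params`.
#' @param params Coefficient table, see [default_k600_params()].
#' @return k600, cm h-1 (non-decreasing in `u10`).
#' @examples
#' k600(0)                        # lake calm-water intercept, 2.07
#' k600(2.5, "small_water_body")
#' @export
k600 <- function(u10, parameterization = "lake", params = default_k600_params()) {
  stopifnot(all(u10 >= 0 | is.na(u10)))
  row <- params[params$parameterization_id == parameterization, ]
  if (nrow(row) != 1) {
    abort(sprintf(
      "k600(): unknown parameterization '%s'; valid ids: %s",
      parameterization, paste(params$parameterization_id, collapse = ", ")
    ))
  }
  row$a + row$b * u10^row$c
}

#' Rescale k600 to the in-situ Schmidt number
#'
#' \eqn{k_t = k_{600} (Sc/600)^{-1/2}}, exactly.
#'
#' @param k600_cm_h Normalized transfer velocity, cm h-1.
#' @param schmidt In-situ Schmidt number.
#' @return kt, cm h-1.
#' @examples
#' kt_from_k600(2, 600)    # 2
#' kt_from_k600(2, 2400)   # 1
#' @export
kt_from_k600 <- function(k600_cm_h, schmidt) {
  stopifnot(all(k600_cm_h > 0 | is.na(k600_cm_h)), all(schmidt > 0 | is.na(schmidt)))
  k600_cm_h * (schmidt / 600)^(-0.5)
}

#' Areal air-water CO2 flux
#'
#' \eqn{F = k_t K_0 (pCO_2^{w} - pCO_2^{a})} with the unit chain:
#' kt (cm h-1) x 0.24 -> m d-1; K0 (mol L-1 atm-1) x pCO2 (uatm) ->
#' umol L-1 = mmol m-3; the product is mmol m-2 d-1.  Positive flux is an
#' efflux from water to atmosphere.
#'
#' @param kt_cm_h Gas-transfer velocity at in-situ Sc, cm h-1.
#' @param k0_mol_l_atm CO2 solubility, mol L-1 atm-1.
#' @param pco2_water_uatm,pco2_atm_uatm Water- and air-side partial pressures.
#' @return Flux, mmol m-2 d-1.
#' @examples
#' areal_flux(1, 0.04, 1380, 380)   # 0.24 * 0.04 * 1000 = 9.6
#' @export
areal_flux <- function(kt_cm_h, k0_mol_l_atm, pco2_water_uatm, pco2_atm_uatm) {
  stopifnot(all(kt_cm_h > 0 | is.na(kt_cm_h)), all(k0_mol_l_atm > 0 | is.na(k0_mol_l_atm)))
  (kt_cm_h * 0.24) * k0_mol_l_atm * (pco2_water_uatm - pco2_atm_uatm)
}

#' Daily regional meteorology from hourly station records
#'
#' Adjusts each wind record to 10 m with [wind_to_10m()], time-averages every
#' variable within station and day, then averages across stations
#' ([spatial_wind_ensemble()] semantics: missing stations drop out of a day's
#' mean; a day with no data at all stays `NA`).
#'
#' @param met_hourly Data frame with `timestamp` (POSIXct or Date),
#'   `station_id`, `wind_m_s`, `sensor_height_m`, and optionally
#'   `air_temp_c`, `pco2_atm_uatm`.
#' @param drag_coefficient Passed to [wind_to_10m()].
#' @return A daily tibble with `date`, `u10_m_s` and, when present in the
#'   input, `pco2_atm_uatm` and `air_temp_c`.
#' @export
daily_meteorology <- function(met_hourly, drag_coefficient = 1.3e-3) {
  stopifnot(all(c("timestamp", "station_id", "wind_m_s", "sensor_height_m")
                %in% names(met_hourly)))
  met <- met_hourly %>%
    as_tibble() %>%
    mutate(
      date = as.Date(.data$timestamp),
      u10_m_s = wind_to_10m(.data$wind_m_s, .data$sensor_height_m, drag_coefficient)
    )
  extras <- intersect(c("pco2_atm_uatm", "air_temp_c"), names(met))
  daily <- met %>%
    group_by(.data$date, .data$station_id) %>%
    summarise(across(all_of(c("u10_m_s", extras)), ~ mean(.x, na.rm = TRUE)),
              .groups = "drop") %>%
    group_by(.data$date) %>%
    summarise(across(all_of(c("u10_m_s", extras)),
                     ~ if (all(is.nan(.x) | is.na(.x))) NA_real_ else
                       mean(.x[!is.nan(.x)], na.rm = TRUE)),
              .groups = "drop") %>%
    arrange(.data$date)
  daily
}
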