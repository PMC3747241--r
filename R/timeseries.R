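# Monthly site samples -> daily series -> annual areal fluxes.
#
# Daily values of temperature, salinity, alkalinity and water pCO2 are
# piecewise-linear interpolations of the roughly monthly measurements, never
# extrapolated beyond the first/last sample.  A site-month with no sample
# because the water level was below the sampling threshold is a hydroperiod
# gap, declared explicitly in `dry_gaps`: interpolation is broken into
# separate wet segments and no flux is fabricated across a dry-down.

interp_daily_series <- function(dates, values, out_dates) {
  ok <- !is.na(values)
  if (sum(ok) == 0) return(rep(NA_real_, length(out_dates)))
  if (sum(ok) == 1) {
    out <- rep(NA_real_, length(out_dates))
    out[out_dates == dates[ok]] <- values[ok]
    return(out)
  }
  approx(as.numeric(dates[ok]), values[ok], xout = as.numeric(out_dates),
         method = "linear", rule = 1)$y
}

#' Interpolate monthly site samples to a daily series
#'
#' Builds, per site, a contiguous daily calendar from the first to the last
#' sampling date and linearly interpolates each requested variable between
#' successive samples.  Interpolated values at sampling dates equal the
#' measurements exactly; nothing is extrapolated outside the sampled span.
#'
#' Declared dry intervals (`dry_gaps`) split the record into wet segments:
#' days inside a gap get `wet_flag = FALSE` and `NA` values, and no
#' interpolation bridges the gap.
#'
#' @param samples Data frame with `site_id`, `date` (Date) and the `vars`
#'   columns; dates strictly increasing within site.
#' @param vars Variables to interpolate.
#' @param dry_gaps Optional data frame with `site_id`, `start`, `end`
#'   (inclusive Dates) marking hydroperiod gaps.
#' @return A tibble with `site_id`, `date`, `wet_flag` and daily `vars`.
#' @export
interpolate_daily <- function(samples,
                              vars = c("temp_c", "salinity", "pco2_uatm", "alk_umol_l"),
                              dry_gaps = NULL) {
  stopifnot(all(c("site_id", "date") %in% names(samples)))
  vars <- intersect(vars, names(samples))
  if (length(vars) == 0) abort("interpolate_daily(): none of `vars` present in `samples`.")

  samples %>%
    as_tibble() %>%
    group_by(.data$site_id) %>%
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$date)
      if (anyDuplicated(df$date)) {
        abort(sprintf("interpolate_daily(): duplicated sampling dates at site %s.", key$site_id))
      }
      gaps <- if (is.null(dry_gaps)) NULL else
        dry_gaps[dry_gaps$site_id == key$site_id, , drop = FALSE]
      if (!is.null(gaps) && nrow(gaps) > 0) {
        for (i in seq_len(nrow(gaps))) {
          if (any(df$date >= gaps$start[i] & df$date <= gaps$end[i])) {
            abort(sprintf(
              "interpolate_daily(): site %s has samples inside a declared dry gap.",
              key$site_id
            ))
          }
        }
      }
      if (nrow(df) == 1) {
        warn(sprintf(
          "interpolate_daily(): site %s has a single sample; returning a one-day series.",
          key$site_id
        ))
        out <- tibble(date = df$date, wet_flag = TRUE)
        for (v in vars) out[[v]] <- df[[v]]
        return(out)
      }
      days <- seq(min(df$date), max(df$date), by = "day")
      dry <- rep(FALSE, length(days))
      seg_of_day <- rep(1L, length(days))
      seg_of_sample <- rep(1L, nrow(df))
      if (!is.null(gaps) && nrow(gaps) > 0) {
        gaps <- arrange(gaps, .data$start)
        for (i in seq_len(nrow(gaps))) {
          dry <- dry | (days >= gaps$start[i] & days <= gaps$end[i])
          seg_of_day <- seg_of_day + (days > gaps$end[i])
          seg_of_sample <- seg_of_sample + (df$date > gaps$end[i])
        }
      }
      out <- tibble(date = days, wet_flag = !dry)
      for (v in vars) out[[v]] <- NA_real_
      for (s in unique(seg_of_sample)) {
        in_seg <- seg_of_day == s & !dry
        smp <- df[seg_of_sample == s, , drop = FALSE]
        sel <- in_seg & days >= min(smp$date) & days <= max(smp$date)
        for (v in vars) {
          out[[v]][sel] <- interp_daily_series(smp$date, smp[[v]], days[sel])
        }
      }
      out
    }) %>%
    ungroup()
}

#' Daily air-water CO2 flux records for interpolated site series
#'
#' For every wet day with an interpolated water pCO2 and available
#' meteorology: the CO2 solubility and Schmidt number are evaluated at the
#' day's interpolated temperature and salinity, the day's ensemble wind gives
#' k600 (rescaled to kt), and the flux follows [areal_flux()] with the day's
#' atmospheric pCO2.  Wet days lacking meteorology are dropped with a logged
#' count (a gap, not a zero).
#'
#' @param site_daily Output of [interpolate_daily()] (needs `pco2_uatm`,
#'   `temp_c`, `salinity`).
#' @param meteo_daily Daily regional meteorology with `date`, `u10_m_s`,
#'   `pco2_atm_uatm` (see [spatial_wind_ensemble()] / [daily_meteorology()]).
#' @param parameterization,params k600 choice, see [k600()].
#' @return A tibble of daily flux records: `site_id`, `date`, `u10_m_s`,
#'   `schmidt`, `k600_cm_h`, `kt_cm_h`, `k0_mol_l_atm`, `pco2_water_uatm`,
#'   `pco2_atm_uatm`, `flux_mmol_m2_d`.
#' @export
daily_fluxes <- function(site_daily, meteo_daily, parameterization = "lake",
                         params = default_k600_params()) {
  stopifnot(all(c("site_id", "date", "wet_flag", "pco2_uatm", "temp_c", "salinity")
                %in% names(site_daily)),
            all(c("date", "u10_m_s", "pco2_atm_uatm") %in% names(meteo_daily)))

  wet <- site_daily %>% filter(.data$wet_flag, !is.na(.data$pco2_uatm))
  joined <- wet %>%
    left_join(meteo_daily %>% select(all_of(c("date", "u10_m_s", "pco2_atm_uatm"))),
              by = "date")
  no_met <- is.na(joined$u10_m_s) | is.na(joined$pco2_atm_uatm)
  if (any(no_met)) {
    inform(sprintf("daily_fluxes(): %d wet day(s) dropped for missing meteorology.",
                   sum(no_met)))
    joined <- joined[!no_met, , drop = FALSE]
  }

  k0 <- carbonate_constants(joined$temp_c, joined$salinity, quiet = TRUE)$k0
  sc <- schmidt_number(joined$temp_c, joined$salinity)
  k6 <- k600(joined$u10_m_s, parameterization, params)
  kt <- kt_from_k600(k6, sc)

  joined %>%
    mutate(
      schmidt = sc, k600_cm_h = k6, kt_cm_h = kt, k0_mol_l_atm = k0,
      pco2_water_uatm = .data$pco2_uatm,
      flux_mmol_m2_d = areal_flux(kt, k0, .data$pco2_uatm, .data$pco2_atm_uatm),
      parameterization_id = parameterization
    ) %>%
    select(all_of(c("site_id", "date", "u10_m_s", "schmidt", "k600_cm_h",
                    "kt_cm_h", "k0_mol_l_atm", "pco2_water_uatm",
                    "pco2_atm_uatm", "flux_mmol_m2_d", "parameterization_id")))
}

#' Annual areal flux per site
#'
#' The annual areal flux is the sum of the daily fluxes (mmol m-2 d-1) over
#' the wet days, divided by 1000: dry days contribute nothing.
#'
#' @param flux_records Output of [daily_fluxes()] (or any frame with
#'   `site_id` and `flux_mmol_m2_d`), spanning at most one year.
#' @return A tibble with `site_id`, `annual_flux_mol_m2_y`, `n_wet_days`.
#' @export
annual_areal_flux <- function(flux_records) {
  stopifnot(all(c("site_id", "flux_mmol_m2_d") %in% names(flux_records)))
  if (nrow(flux_records) == 0) {
    return(tibble(site_id = character(), annual_flux_mol_m2_y = numeric(),
                  n_wet_days = integer()))
  }
  spans <- flux_records %>%
    group_by(.data$site_id) %>%
    summarise(span = as.integer(diff(range(.data$date))) + 1L, .groups = "drop")
  if ("date" %in% names(flux_records) && any(spans$span > 366)) {
    abort("annual_areal_flux(): records span more than one year.")
  }
  flux_records %>%
    group_by(.data$site_id) %>%
    summarise(
      annual_flux_mol_m2_y = sum(.data$flux_mmol_m2_d) / 1000,
      n_wet_days = dplyr::n(),
      .groups = "drop"
    )
}

#' Descriptive statistics of a daily series
#'
#' Mean, median, sd, min, max, range, interquartile range (linear
#' interpolation between order statistics, quantile type 7), moment
#' skewness \eqn{m_3/m_2^{3/2}} and raw (Pearson) kurtosis \eqn{m_4/m_2^2}
#' (not excess: a normal sample sits near 3).  With fewer than two values, or
#' a constant series, the moment statistics are undefined and returned as
#' `NA` with `moments_defined = FALSE`.
#'
#' @param values Numeric vector (NAs dropped).
#' @return A one-row tibble.
#' @examples
#' summary_stats(c(1, 2, 3, 4, 5))
#' @export
summary_stats <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n == 0) {
    return(tibble(n = 0L, mean = NA_real_, median = NA_real_, sd = NA_real_,
                  min = NA_real_, max = NA_real_, range = NA_real_, iqr = NA_real_,
                  skewness = NA_real_, kurtosis = NA_real_, moments_defined = FALSE))
  }
  m <- mean(x)
  s <- if (n >= 2) sd(x) else NA_real_
  m2 <- mean((x - m)^2)
  defined <- n >= 2 && m2 > 0
  tibble(
    n = n, mean = m, median = median(x), sd = s,
    min = min(x), max = max(x), range = max(x) - min(x),
    iqr = unname(quantile(x, 0.75, type = 7) - quantile(x, 0.25, type = 7)),
    skewness = if (defined) mean((x - m)^3) / m2^1.5 else NA_real_,
    kurtosis = if (defined) mean((x - m)^4) / m2^2 else NA_real_,
    moments_defined = defined
  )
}

#' Per-site descriptive statistics of a variable
#'
#' Convenience wrapper applying [summary_stats()] within each site, producing
#' the per-site descriptive tables (water pCO2, daily areal flux) of a
#' monitoring report.
#'
#' @param data A data frame with `site_id` and the `var` column.
#' @param var Name of the variable to summarise.
#' @return A tibble, one row per site.
#' @export
site_summary_table <- function(data, var) {
  stopifnot("site_id" %in% names(data), var %in% names(data))
  data %>%
    group_by(.data$site_id) %>%
    reframe(summary_stats(.data[[var]])) %>%
    ungroup()
}
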