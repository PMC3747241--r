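# Seeded synthetic study: a Mediterranean seasonal-wetland complex.
#
# Eleven monitoring sites in four regions (temporal marshes and
# semi-permanent ponds in a large seasonally flooded wetland, brackish
# managed aquaculture ponds, a dune pond, a small stream), three
# meteorological stations, and a multi-sensor scene series over a toy
# landscape.  Every stochastic element is driven by one integer seed through
# a fixed stream order (seed+1 site chemistry, seed+2 daily meteorology,
# seed+3 hourly elaboration, seed+4 scenes), so any stage can be regenerated
# independently of the others.
#
# All daily "ground truth" follows the operational convention of the
# analysis itself: daily values are linear interpolations of the discrete
# (monthly or per-scene) observations, so the pipeline-recovery tests
# measure the plumbing (wind ensembling, unit chain, summation, areas),
# not an interpolation-model mismatch.

with_stream <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

seasonal_cos <- function(dates, peak_doy, harmonics = 1) {
  doy <- as.numeric(format(dates, "%j"))
  cos(harmonics * 2 * pi * (doy - peak_doy) / 365)
}

#' Configuration of the synthetic wetland study
#'
#' Defines the study conditions the generators realize: one hydrological
#' year (March to February), 11 sites spanning fresh temporal marshes to a
#' mesohaline managed pond with abrupt salinity swings, alkalinities of
#' roughly 1800-6000 umol L-1 with water pCO2 from a few uatm (autumn
#' drawdown) to ~11000 uatm (post-flood heterotrophy), daily winds within
#' 1.3-7.2 m s-1 with median near 2.5 and a spring maximum, atmospheric pCO2
#' within 369-398 uatm, and four regions whose water extent follows the
#' winter-flood / summer-dry cycle (the main wetland peaking near 224 km2 in
#' late February).
#'
#' @param seed Integer seed driving every generator stream.
#' @param n_scenes Number of satellite scenes across the year.
#' @return A list of class `wetflux_config`.
#' @export
synthetic_config <- function(seed = 1, n_scenes = 22) {
  year_start <- as.Date("2010-03-01")
  d <- function(x) as.Date(x)

  sites <- tibble(
    site_id = c("P1", "P2", "P3", "P4", "W1", "W2", "R1", "D1", "T1", "T2", "T3"),
    region_id = c(rep("managed_ponds", 4), "wetlands", "wetlands", "stream",
                  "dune_ponds", "wetlands", "wetlands", "wetlands"),
    archetype = c("managed", "managed", "managed_saline", "managed",
                  "semi_permanent", "semi_permanent", "stream", "dune_pond",
                  "temporal", "temporal", "temporal"),
    sal_median = c(3.1, 2, 18, 5.5, 0.8, 1, 0.2, 0.5, 0.5, 1, 1.2),
    ta_base = c(3000, 3700, 3400, 3200, 4400, 4800, 1800, 2600, 3100, 4600, 5900),
    pco2_b = c(2.65, 2.20, 2.10, 2.45, 2.95, 2.60, 2.90, 2.70, 3.55, 3.35, 3.25),
    pco2_a = c(0.45, 0.35, 0.40, 0.50, 1.00, 0.95, 0.85, 1.30, 0.30, 0.35, 0.30),
    pco2_peak_doy = c(rep(166, 8), rep(196, 3)),   # temporal marshes dip in April
    po4_median = c(0.4, 0.6, 0.4, 0.5, 6, 1.4, 2, 1.2, 12.8, 1.6, 1.4),
    si_median = c(46, 23, 33, 81, 148, 80, 370, 240, 218, 160, 168)
  )

  dry_gaps <- tibble(
    site_id = c("P4", "W1", "T1", "T2", "T3"),
    start = d(c("2010-09-01", "2010-09-01", "2010-06-01", "2010-07-01", "2010-07-01")),
    end = d(c("2010-10-31", "2010-09-30", "2010-11-30", "2010-10-31", "2010-10-31"))
  )

  month_firsts <- seq(d("2010-03-01"), d("2011-03-01"), by = "month")
  area_curve <- function(region_id, values) {
    tibble(region_id = region_id, date = month_firsts, area_km2 = values)
  }
  region_areas <- bind_rows(
    area_curve("wetlands",
               c(120, 150, 110, 60, 15, 3, 1.5, 1.2, 8, 60, 130, 200, 224)),
    area_curve("managed_ponds",
               25 + 11 * seasonal_cos(month_firsts, 30)),
    area_curve("dune_ponds",
               2.05 + 1.95 * seasonal_cos(month_firsts, 15)),
    area_curve("stream",
               0.055 + 0.035 * seasonal_cos(month_firsts, 15))
  )

  # toy landscape (map meters): flood circles inside rectangular region polygons
  region_geometry <- tibble(
    region_id = c("wetlands", "managed_ponds", "dune_ponds", "stream"),
    cx = c(10000, 24000, 24000, 24000),
    cy = c(10500, 5500, 13000, 18000)
  )
  region_polygons <- list(
    wetlands = data.frame(x = c(500, 19500, 19500, 500), y = c(1000, 1000, 20000, 20000)),
    managed_ponds = data.frame(x = c(20000, 28000, 28000, 20000), y = c(1500, 1500, 9500, 9500)),
    dune_ponds = data.frame(x = c(22000, 26000, 26000, 22000), y = c(11000, 11000, 15000, 15000)),
    stream = data.frame(x = c(23000, 25000, 25000, 23000), y = c(17000, 17000, 19000, 19000))
  )
  pif <- tibble(
    x = c(rep(28500 + 250 * 0:4, times = 5), rep(29200, 3)),
    y = c(rep(2000 + 3500 * 0:4, each = 5), 16000, 17000, 18000),
    reflectance = c(seq(0.22, 0.65, length.out = 25), rep(0.035, 3))
  )

  structure(list(
    seed = seed,
    year_start = year_start,
    n_days = 365,
    sites = sites,
    dry_gaps = dry_gaps,
    region_sites = sites %>% select(all_of(c("region_id", "site_id"))),
    region_areas = region_areas,
    stations = tibble(
      station_id = c("st1", "st2", "st3"),
      sensor_height_m = c(10, 2, 10),
      diurnal_amp = c(0.4, 0.6, 0.5)
    ),
    # truth clipped slightly inside the observable envelopes so that daily
    # station means (truth + zero-mean sensor noise) still fall within them
    wind = list(base_log = log(2.35), seasonal_amp = 0.55, peak_doy = 98,
                ar_phi = 0.6, ar_sd = 0.28, min = 1.45, max = 7.05,
                envelope = c(1.3, 7.2)),
    atm = list(base = 380, up = 17.5, down = 10.5, peak_doy = 227,
               ar_phi = 0.7, ar_sd = 0.8, min = 369.3, max = 397.7,
               envelope = c(369, 398)),
    air_temp = list(mean = 19.1, amp = 8.6, peak_doy = 227),
    water_temp = list(mean = 22.65, amp = 9.05, peak_doy = 213, sd = 0.8,
                      min = 13.6, max = 31.7),
    noise = list(pco2_sdlog10 = 0.08, ta_sdlog = 0.05, sal_sdlog = 0.15,
                 nutrient_sdlog = 0.4),
    nutrient_defaults = c(po4 = 2.84, si = 141.91),
    scene = list(
      extent_m = c(30000, 21000),
      pixel_sizes = c(30, 22),
      n_scenes = n_scenes,
      water_refl = 0.06, land_refl = 0.42,
      land_noise_sd = 0.03, water_noise_sd = 0.02, pif_noise_sd = 0.004,
      gain_range = c(0.85, 1.3), offset_range = c(-0.02, 0.05),
      nodata_x_max = 300,
      region_geometry = region_geometry,
      region_polygons = region_polygons,
      pif = pif
    )
  ), class = "wetflux_config")
}

# --- site chemistry ---------------------------------------------------------

site_sampling_dates <- function(config, site, jitter) {
  months <- seq(config$year_start, by = "month", length.out = 12)
  dates <- months + 14 + jitter
  gaps <- config$dry_gaps[config$dry_gaps$site_id == site, , drop = FALSE]
  if (nrow(gaps) > 0) {
    for (i in seq_len(nrow(gaps))) {
      dates <- dates[dates < gaps$start[i] | dates > gaps$end[i]]
    }
  }
  dates
}

# Anchor tables: the "measured" monthly values, noise realized (stream seed+1).
site_anchor_tables <- function(config) {
  with_stream(config$seed + 1, function() {
    out <- purrr::pmap(config$sites, function(site_id, region_id, archetype,
                                              sal_median, ta_base, pco2_b, pco2_a,
                                              pco2_peak_doy, po4_median, si_median) {
      jitter <- round(runif(12, -3, 3))
      dates <- site_sampling_dates(config, site_id, jitter)
      n <- length(dates)

      wt <- config$water_temp
      temp_c <- pmin(pmax(wt$mean + wt$amp * seasonal_cos(dates, wt$peak_doy) +
                            rnorm(n, 0, wt$sd), wt$min), wt$max)
      salinity <- if (archetype == "managed_saline") {
        round(runif(n, 0, 50), 1)          # abrupt management-driven swings
      } else {
        pmin(sal_median * exp(rnorm(n, 0, config$noise$sal_sdlog)), 50)
      }
      alk <- pmin(pmax(ta_base * exp(0.08 * seasonal_cos(dates, 227)) *
                         exp(rnorm(n, 0, config$noise$ta_sdlog)), 1500), 6500)
      lp <- pco2_b + pco2_a * seasonal_cos(dates, pco2_peak_doy, harmonics = 2) +
        rnorm(n, 0, config$noise$pco2_sdlog10)
      pco2 <- pmin(pmax(10^lp, 5), 11000)

      po4 <- po4_median * exp(rnorm(n, 0, config$noise$nutrient_sdlog))
      si <- si_median * exp(rnorm(n, 0, config$noise$nutrient_sdlog))

      tibble(site_id = site_id, date = dates, temp_c = temp_c,
             salinity = salinity, alk_umol_l = alk, pco2_true_uatm = pco2,
             po4_true = po4, si_true = si)
    })
    bind_rows(out) %>%
      mutate(
        # nutrient analyses missing for every site in the final month (and one
        # managed-pond sample), mirroring how monitoring data arrive
        na_nutrients = format(.data$date, "%Y-%m") == "2011-02" |
          (.data$site_id == "P3" & format(.data$date, "%Y-%m") == "2010-05")
      )
  })
}

#' Generate monthly water-sample tables
#'
#' Emits one year of roughly monthly samples for the 11 synthetic sites.
#' For each sample a target water pCO2 is drawn from the site's seasonal
#' curve (log-normal noise) and the NBS pH consistent with the drawn
#' alkalinity, temperature, salinity and nutrients is obtained with
#' [ph_for_pco2()], so speciating the emitted (pH, TA) pair returns the
#' generator's pCO2 exactly.  Temporal-marsh sites are not sampled during
#' their dry window; some nutrient values are `NA` to exercise
#' [fill_missing_nutrients()].
#'
#' @param config A [synthetic_config()].
#' @return A tibble of water samples (`site_id`, `date`, `temp_c`,
#'   `salinity`, `ph_nbs`, `alk_umol_l`, `po4_umol_l`, `sioh4_umol_l`,
#'   `pressure_dbar`).
#' @export
generate_sites <- function(config) {
  anchors <- site_anchor_tables(config)
  nd <- config$nutrient_defaults
  po4_eff <- ifelse(anchors$na_nutrients, nd[["po4"]], anchors$po4_true)
  si_eff <- ifelse(anchors$na_nutrients, nd[["si"]], anchors$si_true)
  ph <- ph_for_pco2(anchors$pco2_true_uatm, anchors$alk_umol_l,
                    anchors$temp_c, anchors$salinity, po4_eff, si_eff)
  anchors %>%
    mutate(
      ph_nbs = ph,
      po4_umol_l = ifelse(.data$na_nutrients, NA_real_, .data$po4_true),
      sioh4_umol_l = ifelse(.data$na_nutrients, NA_real_, .data$si_true),
      pressure_dbar = 0
    ) %>%
    select(all_of(c("site_id", "date", "temp_c", "salinity", "ph_nbs",
                    "alk_umol_l", "po4_umol_l", "sioh4_umol_l", "pressure_dbar")))
}

# --- meteorology ------------------------------------------------------------

ar1 <- function(n, phi, sd) {
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd / sqrt(1 - phi^2))
  for (i in seq_len(n - 1)) x[i + 1] <- phi * x[i] + rnorm(1, 0, sd)
  x
}

# Daily regional truth for wind and atmospheric pCO2 (stream seed+2).
daily_met_truth <- function(config) {
  with_stream(config$seed + 2, function() {
    dates <- seq(config$year_start, by = "day", length.out = config$n_days)
    w <- config$wind
    u <- exp(w$base_log + w$seasonal_amp * seasonal_cos(dates, w$peak_doy) +
               ar1(config$n_days, w$ar_phi, w$ar_sd))
    u <- pmin(pmax(u, w$min), w$max)

    a <- config$atm
    cs <- seasonal_cos(dates, a$peak_doy)
    p <- a$base + a$up * pmax(cs, 0) - a$down * pmax(-cs, 0) +
      ar1(config$n_days, a$ar_phi, a$ar_sd)
    p <- pmin(pmax(p, a$min), a$max)

    at <- config$air_temp
    tair <- at$mean + at$amp * seasonal_cos(dates, at$peak_doy)

    tibble(date = dates, u10_true_m_s = u, pco2_atm_true_uatm = p,
           air_temp_true_c = tair)
  })
}

#' Generate hourly meteorological station records
#'
#' Elaborates the daily regional truth (seasonal wind with a spring maximum,
#' AR(1) day-to-day persistence, daily means confined to 1.3-7.2 m s-1 with
#' median near 2.5; atmospheric pCO2 in 369-398 uatm peaking in late summer)
#' into hourly records at three stations with correlated noise, per-station
#' diurnal cycles with zero daily mean, and one station mounted at 2 m so the
#' height adjustment is exercised.  Averaging the output back to daily
#' regional values recovers the truth to within the station noise.
#'
#' @param config A [synthetic_config()].
#' @return An hourly tibble: `timestamp`, `station_id`, `wind_m_s`,
#'   `sensor_height_m`, `air_temp_c`, `pco2_atm_uatm`.
#' @export
generate_meteorology <- function(config) {
  truth <- daily_met_truth(config)
  z0 <- 10 / exp(0.4 / sqrt(1.3e-3))
  with_stream(config$seed + 3, function() {
    hours <- seq(0, 23)
    out <- purrr::pmap(config$stations, function(station_id, sensor_height_m,
                                                 diurnal_amp) {
      n_h <- nrow(truth) * 24
      diurnal <- diurnal_amp * sin(2 * pi * (rep(hours, nrow(truth)) - 9) / 24)
      u10 <- rep(truth$u10_true_m_s, each = 24) + diurnal + rnorm(n_h, 0, 0.3)
      u10 <- pmax(u10, 0.05)
      # record at sensor height via the same neutral log profile
      u_z <- u10 * log(sensor_height_m / z0) / log(10 / z0)
      tibble(
        timestamp = rep(as.POSIXct(truth$date, tz = "UTC"), each = 24) +
          rep(hours, nrow(truth)) * 3600,
        station_id = station_id,
        wind_m_s = u_z,
        sensor_height_m = sensor_height_m,
        air_temp_c = rep(truth$air_temp_true_c, each = 24) +
          4 * sin(2 * pi * (rep(hours, nrow(truth)) - 15) / 24) +
          rnorm(n_h, 0, 0.6),
        pco2_atm_uatm = rep(truth$pco2_atm_true_uatm, each = 24) +
          rnorm(n_h, 0, 0.5)
      )
    })
    bind_rows(out)
  })
}

# --- scenes -----------------------------------------------------------------

scene_dates_for <- function(config) {
  config$year_start + round(seq(5, config$n_days - 6,
                                length.out = config$scene$n_scenes))
}

region_area_truth_daily <- function(config) {
  config$region_areas %>%
    group_by(.data$region_id) %>%
    dplyr::group_modify(function(df, key) {
      days <- seq(config$year_start, by = "day", length.out = config$n_days)
      tibble(date = days,
             area_km2 = approx(as.numeric(df$date), df$area_km2,
                               xout = as.numeric(days), rule = 1)$y)
    }) %>%
    ungroup()
}

#' Generate a multi-sensor reflectance-scene series with region polygons
#'
#' Builds one toy landscape per scene date: seasonally flooded circles (one
#' per region, radius set by the region's true water area that day) with NIR
#' reflectance well below the 0.2 water threshold, brighter land, a strip of
#' nodata, stable pseudo-invariant features (PIFs), and a per-scene linear
#' radiometric distortion (gain/offset) that [normalize_scene()] must undo.
#' Scenes alternate between 30 m and 22 m ground resolution.
#'
#' @param config A [synthetic_config()].
#' @return A list with `scenes` (list of [reflectance_scene()]), `pif`
#'   (map-coordinate PIF table), `region_polygons`, `scene_dates`, and the
#'   applied `distortions`.
#' @export
generate_scenes <- function(config) {
  sc <- config$scene
  dates <- scene_dates_for(config)
  truth <- region_area_truth_daily(config)
  geom <- sc$region_geometry

  with_stream(config$seed + 4, function() {
    gains <- c(1, runif(length(dates) - 1, sc$gain_range[1], sc$gain_range[2]))
    offsets <- c(0, runif(length(dates) - 1, sc$offset_range[1], sc$offset_range[2]))

    scenes <- vector("list", length(dates))
    for (k in seq_along(dates)) {
      px <- sc$pixel_sizes[(k - 1) %% length(sc$pixel_sizes) + 1]
      nc <- floor(sc$extent_m[1] / px)
      nr <- floor(sc$extent_m[2] / px)
      nir <- matrix(rnorm(nr * nc, sc$land_refl, sc$land_noise_sd), nrow = nr)

      xc <- (seq_len(nc) - 0.5) * px
      yc <- (seq_len(nr) - 0.5) * px
      day_areas <- truth[truth$date == dates[k], , drop = FALSE]
      for (g in seq_len(nrow(geom))) {
        area <- day_areas$area_km2[day_areas$region_id == geom$region_id[g]]
        r <- sqrt(area * 1e6 / pi)
        jc <- which(abs(xc - geom$cx[g]) <= r)
        ic <- which(abs(yc - geom$cy[g]) <= r)
        if (length(jc) == 0 || length(ic) == 0) next
        sub <- outer(yc[ic] - geom$cy[g], xc[jc] - geom$cx[g],
                     function(dy, dx) dy^2 + dx^2) <= r^2
        nw <- sum(sub)
        block <- nir[ic, jc, drop = FALSE]
        block[sub] <- rnorm(nw, sc$water_refl, sc$water_noise_sd)
        nir[ic, jc] <- block
      }
      # pseudo-invariant features: fixed map positions, stable reflectance
      pif_col <- pmin(pmax(ceiling(sc$pif$x / px), 1), nc)
      pif_row <- pmin(pmax(ceiling(sc$pif$y / px), 1), nr)
      nir[cbind(pif_row, pif_col)] <- sc$pif$reflectance +
        rnorm(nrow(sc$pif), 0, sc$pif_noise_sd)

      nir <- pmin(pmax(gains[k] * nir + offsets[k], 0), 1)
      nir[, xc < sc$nodata_x_max] <- NA_real_

      scenes[[k]] <- reflectance_scene(nir, px, date = dates[k])
    }
    list(scenes = scenes, pif = sc$pif, region_polygons = sc$region_polygons,
         scene_dates = dates,
         distortions = tibble(date = dates, gain = gains, offset = offsets))
  })
}

# --- ground truth for recovery tests ---------------------------------------

# Piecewise-linear daily interpolation of site anchors within wet segments,
# written independently of interpolate_daily() on purpose.
truth_site_daily <- function(config, anchors) {
  purrr::map(unique(anchors$site_id), function(sid) {
    df <- anchors[anchors$site_id == sid, , drop = FALSE]
    df <- df[order(df$date), , drop = FALSE]
    gaps <- config$dry_gaps[config$dry_gaps$site_id == sid, , drop = FALSE]
    seg <- rep(1L, nrow(df))
    if (nrow(gaps) > 0) {
      for (i in seq_len(nrow(gaps))) seg <- seg + (df$date > gaps$end[i])
    }
    purrr::map(unique(seg), function(s) {
      smp <- df[seg == s, , drop = FALSE]
      if (nrow(smp) < 2) return(NULL)
      days <- seq(min(smp$date), max(smp$date), by = "day")
      li <- function(v) approx(as.numeric(smp$date), v, xout = as.numeric(days))$y
      tibble(site_id = sid, date = days, temp_c = li(smp$temp_c),
             salinity = li(smp$salinity), pco2_uatm = li(smp$pco2_true_uatm))
    }) %>% bind_rows()
  }) %>% bind_rows()
}

#' Closed-form expectations for the synthetic study
#'
#' Recomputes, from the generator's own anchor values and daily truth
#' series (regenerated from the seed; no pipeline functions involved), the
#' expected daily and annual areal flux per site and the expected daily and
#' annual carbon transport per region.  Pipeline-recovery tests compare the
#' analysis output against these numbers.
#'
#' @param config A [synthetic_config()].
#' @return A list with `met_daily`, `site_daily`, `site_annual`,
#'   `region_daily`, `region_annual`, `area_daily`.
#' @export
synthetic_truth <- function(config) {
  anchors <- site_anchor_tables(config)
  met <- daily_met_truth(config)
  site_daily <- truth_site_daily(config, anchors) %>%
    left_join(met, by = "date")

  tk <- site_daily$temp_c + 273.15
  k0 <- exp(-58.0931 + 90.5069 * (100 / tk) + 22.2940 * log(tk / 100) +
              site_daily$salinity * (0.027766 - 0.025888 * (tk / 100) +
                                       0.0050578 * (tk / 100)^2))
  t <- site_daily$temp_c
  sc0 <- 1923.6 - 125.06 * t + 4.3773 * t^2 - 0.085681 * t^3 + 0.00070284 * t^4
  sc35 <- 2116.8 - 136.25 * t + 4.7353 * t^2 - 0.092307 * t^3 + 0.0007555 * t^4
  sc <- sc0 + (sc35 - sc0) * site_daily$salinity / 35
  k6 <- 2.07 + 0.215 * site_daily$u10_true_m_s^1.7
  kt <- k6 * sqrt(600 / sc)
  site_daily$flux_mmol_m2_d <- 0.24 * kt * k0 *
    (site_daily$pco2_uatm - site_daily$pco2_atm_true_uatm)

  site_annual <- site_daily %>%
    group_by(.data$site_id) %>%
    summarise(annual_flux_mol_m2_y = sum(.data$flux_mmol_m2_d) / 1000,
              n_wet_days = dplyr::n(), .groups = "drop")

  area_daily <- region_area_truth_daily(config)
  region_daily <- site_daily %>%
    left_join(config$region_sites, by = "site_id") %>%
    group_by(.data$region_id, .data$date) %>%
    summarise(mean_flux_mmol_m2_d = mean(.data$flux_mmol_m2_d), .groups = "drop") %>%
    inner_join(area_daily, by = c("region_id", "date")) %>%
    mutate(transport_g_c_d = .data$mean_flux_mmol_m2_d * 1e-3 *
             .data$area_km2 * 1e6 * 12.011)
  region_annual <- region_daily %>%
    group_by(.data$region_id) %>%
    summarise(annual_transport_gg_c_y = sum(.data$transport_g_c_d) / 1e9,
              .groups = "drop")

  list(met_daily = met, site_daily = site_daily, site_annual = site_annual,
       region_daily = region_daily, region_annual = region_annual,
       area_daily = area_daily)
}
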