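# End-to-end orchestration: samples + meteorology (+ scenes) -> speciation ->
# daily fluxes -> annual areal fluxes -> regional transport -> summary tables.

#' Validate a water-sample table
#'
#' Checks the schema and physical ranges of a sample table: temperature
#' 0-45 C, salinity 0-50, pH (NBS) 4-11, positive alkalinity, non-negative
#' nutrients, parseable dates.
#'
#' @param samples A data frame of water samples.
#' @return Invisibly, a tibble of issues (zero rows when clean).
#' @param stop_on_error Abort with an itemized report when issues are found.
#' @export
validate_water_samples <- function(samples, stop_on_error = TRUE) {
  issues <- list()
  note <- function(msg) issues[[length(issues) + 1]] <<- msg
  required <- c("site_id", "date", "temp_c", "salinity", "ph_nbs", "alk_umol_l")
  miss <- setdiff(required, names(samples))
  if (length(miss) > 0) {
    note(paste("missing columns:", paste(miss, collapse = ", ")))
  } else {
    bad <- function(cond, what) {
      idx <- which(cond)
      if (length(idx) > 0) {
        note(sprintf("%s in %d row(s): e.g. row %d (site %s)", what,
                     length(idx), idx[1], samples$site_id[idx[1]]))
      }
    }
    bad(is.na(samples$temp_c) | samples$temp_c < 0 | samples$temp_c > 45,
        "temperature outside 0-45 C")
    bad(is.na(samples$salinity) | samples$salinity < 0 | samples$salinity > 50,
        "salinity outside 0-50")
    bad(is.na(samples$ph_nbs) | samples$ph_nbs < 4 | samples$ph_nbs > 11,
        "pH outside 4-11")
    bad(is.na(samples$alk_umol_l) | samples$alk_umol_l <= 0,
        "non-positive alkalinity")
    for (nut in intersect(c("po4_umol_l", "sioh4_umol_l"), names(samples))) {
      bad(!is.na(samples[[nut]]) & samples[[nut]] < 0,
          paste("negative", nut))
    }
  }
  issues <- tibble(issue = unlist(issues) %||% character())
  if (stop_on_error && nrow(issues) > 0) {
    abort(c("invalid water-sample table:", setNames(issues$issue, rep("x", nrow(issues)))))
  }
  invisible(issues)
}

#' Water areas per region and scene
#'
#' Normalizes each scene against a reference scene using the
#' pseudo-invariant features, classifies water by the NIR threshold and
#' counts water pixels inside each region polygon.
#'
#' @param scene_set A list with `scenes`, `pif` and `region_polygons` (the
#'   shape produced by [generate_scenes()]).
#' @param threshold NIR water threshold, see [classify_water()].
#' @param normalize Apply [normalize_scene()] (reference = first scene).
#' @param reference_index Which scene anchors the radiometry.
#' @return A tibble with `region_id`, `date`, `area_km2`.
#' @export
scene_water_areas <- function(scene_set, threshold = 0.2, normalize = TRUE,
                              reference_index = 1) {
  scenes <- scene_set$scenes
  reference <- scenes[[reference_index]]
  out <- purrr::map(scenes, function(scn) {
    if (normalize && !is.null(scene_set$pif)) {
      scn <- normalize_scene(scn, reference, scene_set$pif)
    }
    mask <- classify_water(scn, threshold)
    areas <- purrr::map_dbl(scene_set$region_polygons, function(poly) {
      region_water_area(mask, scn, poly)
    })
    tibble(region_id = names(areas), date = scn$date, area_km2 = unname(areas))
  })
  bind_rows(out) %>% arrange(.data$region_id, .data$date)
}

#' Compare k600 parameterizations through the full pipeline
#'
#' Reruns the daily-flux and annual-integration chain once per
#' parameterization and reports the signed percentage difference of the
#' annual total against the lake default.  When region membership and daily
#' areas are supplied the aggregate is the total regional carbon transport
#' (Gg C y-1); otherwise it is the sum of the per-site annual areal fluxes.
#'
#' @param site_daily Interpolated daily site series ([interpolate_daily()]).
#' @param meteo_daily Daily meteorology ([daily_meteorology()]).
#' @param ids Parameterization ids to run.
#' @param params Coefficient table ([default_k600_params()]).
#' @param region_sites,area_daily Optional region membership and daily areas.
#' @param baseline Id used as the 0% reference.
#' @return A tibble with `parameterization_id`, `annual_total`, `unit`,
#'   `pct_diff_vs_baseline`.
#' @export
compare_parameterizations <- function(site_daily, meteo_daily,
                                      ids = c("lake", "small_water_body", "ocean"),
                                      params = default_k600_params(),
                                      region_sites = NULL, area_daily = NULL,
                                      baseline = "lake") {
  if (!baseline %in% ids) baseline <- ids[1]
  use_transport <- !is.null(region_sites) && !is.null(area_daily)
  totals <- purrr::map_dbl(setNames(ids, ids), function(id) {
    fx <- daily_fluxes(site_daily, meteo_daily, parameterization = id, params = params)
    if (use_transport) {
      tr <- regional_daily_transport(fx, region_sites, area_daily)
      sum(tr$transport_g_c_d) / 1e9
    } else {
      sum(annual_areal_flux(fx)$annual_flux_mol_m2_y)
    }
  })
  tibble(
    parameterization_id = ids,
    annual_total = unname(totals),
    unit = if (use_transport) "Gg C y-1" else "mol m-2 y-1 (summed over sites)",
    pct_diff_vs_baseline = unname(100 * (totals - totals[baseline]) / abs(totals[baseline]))
  )
}

#' Combined annual budget summaries
#'
#' The two headline numbers of an annual assessment: the across-site mean
#' annual areal flux and the summed regional carbon transport.
#'
#' @param site_annual_flux_mol_m2_y Per-site annual areal fluxes.
#' @param region_transport_gg_c_y Per-region annual transports.
#' @return A one-row tibble with `n_sites`, `mean_site_annual_flux_mol_m2_y`,
#'   `n_regions`, `total_transport_gg_c_y`.
#' @export
annual_budget <- function(site_annual_flux_mol_m2_y, region_transport_gg_c_y = numeric()) {
  tibble(
    n_sites = length(site_annual_flux_mol_m2_y),
    mean_site_annual_flux_mol_m2_y = mean(site_annual_flux_mol_m2_y),
    n_regions = length(region_transport_gg_c_y),
    total_transport_gg_c_y = if (length(region_transport_gg_c_y) > 0)
      sum(region_transport_gg_c_y) else NA_real_
  )
}

#' Run the full air-water CO2 analysis
#'
#' Orchestrates the whole chain: sample validation, nutrient filling,
#' carbonate speciation, monthly-to-daily interpolation with declared
#' hydroperiod gaps, daily meteorology, daily and annual areal fluxes,
#' descriptive statistics, optional remote-sensing up-scaling to regional
#' carbon transport, the k600 sensitivity comparison, and an optional NPP
#' comparison.
#'
#' @param samples Monthly water samples (see [validate_water_samples()]).
#' @param met_hourly Hourly station meteorology (see [daily_meteorology()]).
#' @param dry_gaps Declared per-site dry intervals ([interpolate_daily()]).
#' @param region_sites Region membership table (`region_id`, `site_id`).
#' @param scene_areas Per-scene region water areas (`region_id`, `date`,
#'   `area_km2`), if already classified.
#' @param scene_set Raw scene list ([generate_scenes()] shape); classified
#'   internally when `scene_areas` is not given.
#' @param parameterization,k600_params Primary k600 choice.
#' @param sensitivity_ids Parameterizations for the sensitivity table.
#' @param npp_mol_m2_y,npp_area_km2 Optional NPP comparison inputs.
#' @param nutrient_defaults Defaults for [fill_missing_nutrients()].
#' @param nir_threshold Water classification threshold.
#' @param quiet Silence progress messages.
#' @return A `wetflux_run` object: a list of tibbles (`speciated`,
#'   `site_daily`, `flux_daily`, `site_annual`, `pco2_stats`, `flux_stats`,
#'   `area_daily`, `region_daily`, `region_annual`, `annual_table`,
#'   `sensitivity`, `npp`, `budget`) plus `meta`.
#' @export
run_pipeline <- function(samples, met_hourly, dry_gaps = NULL,
                         region_sites = NULL, scene_areas = NULL, scene_set = NULL,
                         parameterization = "lake",
                         k600_params = default_k600_params(),
                         sensitivity_ids = c("lake", "small_water_body", "ocean"),
                         npp_mol_m2_y = NULL, npp_area_km2 = NULL,
                         nutrient_defaults = c(po4 = 2.84, si = 141.91),
                         nir_threshold = 0.2, quiet = FALSE) {
  say <- function(...) if (!quiet) inform(sprintf(...))
  validate_water_samples(samples)
  say("speciating %d samples from %d sites", nrow(samples),
      length(unique(samples$site_id)))

  speciated <- samples %>%
    fill_missing_nutrients(nutrient_defaults[["po4"]], nutrient_defaults[["si"]]) %>%
    speciate(quiet = TRUE)

  site_daily <- interpolate_daily(
    speciated %>% filter(.data$speciation_ok),
    vars = c("temp_c", "salinity", "pco2_uatm", "alk_umol_l"),
    dry_gaps = dry_gaps
  )
  meteo_daily <- daily_meteorology(met_hourly)
  flux_daily <- daily_fluxes(site_daily, meteo_daily,
                             parameterization = parameterization,
                             params = k600_params)
  site_annual <- annual_areal_flux(flux_daily)
  say("daily fluxes on %d site-days; %d sites with annual integrals",
      nrow(flux_daily), nrow(site_annual))

  pco2_stats <- site_summary_table(
    speciated %>% filter(.data$speciation_ok), "pco2_uatm")
  flux_stats <- site_summary_table(flux_daily, "flux_mmol_m2_d")

  area_daily <- region_daily <- region_annual <- annual_table <- NULL
  if (is.null(scene_areas) && !is.null(scene_set)) {
    say("classifying %d scenes", length(scene_set$scenes))
    scene_areas <- scene_water_areas(scene_set, threshold = nir_threshold)
  }
  if (!is.null(scene_areas) && !is.null(region_sites)) {
    area_daily <- interpolate_area_daily(scene_areas)
    region_daily <- regional_daily_transport(flux_daily, region_sites, area_daily)
    region_annual <- region_daily %>%
      group_by(.data$region_id) %>%
      summarise(annual_transport_gg_c_y = sum(.data$transport_g_c_d) / 1e9,
                area_min_km2 = min(.data$area_km2),
                area_max_km2 = max(.data$area_km2), .groups = "drop")
    annual_table <- site_annual %>%
      left_join(as_tibble(region_sites), by = "site_id") %>%
      left_join(region_annual, by = "region_id") %>%
      select(all_of(c("region_id", "site_id", "annual_flux_mol_m2_y",
                      "n_wet_days", "area_min_km2", "area_max_km2",
                      "annual_transport_gg_c_y")))
  }

  sensitivity <- compare_parameterizations(
    site_daily, meteo_daily, ids = sensitivity_ids, params = k600_params,
    region_sites = region_sites, area_daily = area_daily
  )

  budget <- annual_budget(
    site_annual$annual_flux_mol_m2_y,
    if (!is.null(region_annual)) region_annual$annual_transport_gg_c_y else numeric()
  )

  npp <- NULL
  if (!is.null(npp_mol_m2_y) && !is.null(npp_area_km2)) {
    npp <- npp_comparison(npp_mol_m2_y, npp_area_km2,
                          budget$total_transport_gg_c_y)
  }

  meta <- list(
    package_version = as.character(utils::packageVersion("wetflux")),
    parameterization = parameterization,
    nir_threshold = nir_threshold,
    nutrient_defaults = nutrient_defaults,
    config_hash = rlang::hash(list(samples, met_hourly, dry_gaps, region_sites,
                                   scene_areas, parameterization, k600_params,
                                   sensitivity_ids, nutrient_defaults,
                                   nir_threshold))
  )

  structure(list(
    speciated = speciated, site_daily = site_daily, flux_daily = flux_daily,
    site_annual = site_annual, pco2_stats = pco2_stats, flux_stats = flux_stats,
    scene_areas = scene_areas, area_daily = area_daily,
    region_daily = region_daily, region_annual = region_annual,
    annual_table = annual_table, sensitivity = sensitivity, npp = npp,
    budget = budget, meta = meta
  ), class = "wetflux_run")
}

#' @export
print.wetflux_run <- function(x, ...) {
  cat("<wetflux_run>\n")
  cat(sprintf("  sites: %d  |  site-days with flux: %d\n",
              nrow(x$site_annual), nrow(x$flux_daily)))
  cat(sprintf("  mean annual areal flux: %.2f mol m-2 y-1\n",
              x$budget$mean_site_annual_flux_mol_m2_y))
  if (!is.na(x$budget$total_transport_gg_c_y)) {
    cat(sprintf("  total annual C transport: %.2f Gg C y-1 over %d regions\n",
                x$budget$total_transport_gg_c_y, x$budget$n_regions))
  }
  cat(sprintf("  k600: %s  |  config hash %s\n",
              x$meta$parameterization, substr(x$meta$config_hash, 1, 8)))
  invisible(x)
}

#' Tidy the per-site annual results of a run
#'
#' @param x A `wetflux_run`.
#' @param ... Unused.
#' @return The annual per-site table (with regional columns when up-scaling
#'   was run), one row per site.
#' @method tidy wetflux_run
#' @export
tidy.wetflux_run <- function(x, ...) {
  if (!is.null(x$annual_table)) x$annual_table else x$site_annual
}

#' One-row summary of a run
#'
#' @param x A `wetflux_run`.
#' @param ... Unused.
#' @return A one-row tibble with the headline annual budget numbers.
#' @method glance wetflux_run
#' @export
glance.wetflux_run <- function(x, ...) {
  x$budget %>%
    mutate(parameterization = x$meta$parameterization,
           config_hash = x$meta$config_hash)
}

#' Plot the daily results of a run
#'
#' @param object A `wetflux_run`.
#' @param type `"flux"` (daily areal flux per site), `"pco2"` (measured
#'   water pCO2 at sampling dates), or `"area"` (regional water extent).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wetflux_run
#' @export
autoplot.wetflux_run <- function(object, type = c("flux", "pco2", "area"), ...) {
  type <- match.arg(type)
  if (type == "flux") {
    ggplot2::ggplot(object$flux_daily,
                    ggplot2::aes(x = .data$date, y = .data$flux_mmol_m2_d)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
      ggplot2::geom_line(colour = "#2166ac") +
      ggplot2::facet_wrap(~site_id, scales = "free_y") +
      ggplot2::labs(x = NULL, y = expression(F[CO[2]]~(mmol~m^-2~d^-1)))
  } else if (type == "pco2") {
    ggplot2::ggplot(object$speciated,
                    ggplot2::aes(x = .data$date, y = .data$pco2_uatm)) +
      ggplot2::geom_line(colour = "grey40") +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::scale_y_log10() +
      ggplot2::facet_wrap(~site_id) +
      ggplot2::labs(x = NULL, y = expression(pCO[2]~(mu*atm)))
  } else {
    if (is.null(object$area_daily)) {
      abort("autoplot(type = 'area'): run had no up-scaling stage.")
    }
    ggplot2::ggplot(object$area_daily,
                    ggplot2::aes(x = .data$date, y = .data$area_km2)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~region_id, scales = "free_y") +
      ggplot2::labs(x = NULL, y = expression(Water~extent~(km^2)))
  }
}
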