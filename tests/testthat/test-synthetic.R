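test_that("every generator is deterministic under the seed, stream by stream", {
  cfg <- synthetic_config(seed = 42)
  expect_identical(generate_sites(cfg), fx_samples())
  expect_identical(generate_meteorology(cfg), fx_met())
  expect_identical(synthetic_truth(cfg)$site_annual, fx_truth()$site_annual)

  # streams are independent: meteorology is the same whether or not the site
  # generator ran first
  met_alone <- generate_meteorology(synthetic_config(seed = 42))
  expect_identical(met_alone, fx_met())

  sc <- generate_scenes(cfg)
  expect_identical(sc$distortions, fx_scenes()$distortions)
  expect_identical(sc$scenes[[3]]$nir[1:50, 1:50], fx_scenes()$scenes[[3]]$nir[1:50, 1:50])
})

test_that("site tables respect archetype envelopes and hydroperiods", {
  cfg <- fx_config()
  s <- fx_samples()
  expect_setequal(unique(s$site_id), cfg$sites$site_id)
  expect_true(all(s$salinity >= 0 & s$salinity <= 50))
  expect_true(all(s$ph_nbs > 4 & s$ph_nbs < 11))
  expect_true(all(s$alk_umol_l > 1000 & s$alk_umol_l < 7000))

  # no samples inside any declared dry window
  for (i in seq_len(nrow(cfg$dry_gaps))) {
    g <- cfg$dry_gaps[i, ]
    inside <- s$site_id == g$site_id & s$date >= g$start & s$date <= g$end
    expect_equal(sum(inside), 0)
  }
  # the managed saline pond swings across the full salinity range
  p3 <- s$salinity[s$site_id == "P3"]
  expect_gt(max(p3) - min(p3), 20)
})

test_that("implied water pCO2 spans super- and under-saturation", {
  sp <- suppressWarnings(speciate(fill_missing_nutrients(fx_samples()), quiet = TRUE))
  expect_true(all(sp$speciation_ok))
  expect_lt(min(sp$pco2_uatm), 200)     # autumn drawdown, strongly undersaturated
  expect_gt(max(sp$pco2_uatm), 5000)    # flood-season supersaturation
  # and within each year both regimes occur across the site network
  expect_gt(mean(sp$pco2_uatm > 398), 0.3)
  expect_gt(mean(sp$pco2_uatm < 369), 0.1)
})

test_that("daily station means stay inside the meteorological envelopes", {
  md <- daily_meteorology(fx_met())
  expect_true(all(md$u10_m_s >= 1.3 & md$u10_m_s <= 7.2))
  expect_gt(median(md$u10_m_s), 2)
  expect_lt(median(md$u10_m_s), 3)
  expect_true(all(md$pco2_atm_uatm >= 369 & md$pco2_atm_uatm <= 398))
  expect_equal(median(md$pco2_atm_uatm), 380, tolerance = 0.02)

  # stations share the regional signal: daily means correlate strongly
  met <- fx_met()
  met$date <- as.Date(met$timestamp)
  st <- dplyr::summarise(dplyr::group_by(met, date, station_id),
                         u = mean(wind_to_10m(wind_m_s, sensor_height_m[1])),
                         .groups = "drop")
  wide <- tidyr::pivot_wider(st, names_from = "station_id", values_from = "u")
  expect_gt(stats::cor(wide$st1, wide$st2), 0.9)
})

test_that("scene classification recovers the configured water areas", {
  cfg <- fx_config()
  sc <- fx_scenes()
  truth_daily <- fx_truth()$area_daily

  # the undistorted reference scene, no normalization needed
  scn <- sc$scenes[[1]]
  mask <- classify_water(scn)
  for (rid in c("wetlands", "managed_ponds")) {
    got <- region_water_area(mask, scn, sc$region_polygons[[rid]])
    want <- truth_daily$area_km2[truth_daily$region_id == rid &
                                   truth_daily$date == scn$date]
    expect_equal(got, want, tolerance = 0.01)
  }
})

test_that("a known radiometric distortion is undone to within 1% of truth", {
  sc <- fx_scenes()
  ref <- sc$scenes[[1]]
  poly <- sc$region_polygons$wetlands
  area_ref <- region_water_area(classify_water(ref), ref, poly)

  # apply a known gain of 1.3 to the clean scene, then normalize it back
  distorted <- ref
  distorted$nir <- pmin(1.3 * ref$nir, 1)
  recovered <- normalize_scene(distorted, ref, sc$pif)
  area_rec <- region_water_area(classify_water(recovered), recovered, poly)
  expect_equal(area_rec, area_ref, tolerance = 0.01)

  # and the generator's own per-scene distortions are recoverable too
  k <- which.max(abs(sc$distortions$gain - 1))
  norm_k <- normalize_scene(sc$scenes[[k]], ref, sc$pif)
  expect_equal(norm_k$normalization$slope * sc$distortions$gain[k], 1,
               tolerance = 0.05)
})
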