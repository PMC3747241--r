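test_that("CO2 solubility matches the independent reference and cools out of solution", {
  g <- oracle_grid()
  ref <- unique(g[, c("temp_c", "salinity", "k0_mol_l_atm")])
  k0 <- carbonate_constants(ref$temp_c, ref$salinity, quiet = TRUE)$k0
  expect_lt(max(abs(k0 - ref$k0_mol_l_atm) / ref$k0_mol_l_atm), 0.02)

  # strictly decreasing in temperature at fixed salinity
  for (s in c(0, 18, 35)) {
    k <- carbonate_constants(seq(0, 35, by = 2.5), s, quiet = TRUE)$k0
    expect_true(all(diff(k) < 0))
  }
})

test_that("carbonic acid constants are ordered K1 >> K2", {
  k <- carbonate_constants(25, 35)
  expect_gt(k$k1, k$k2)
  ratio <- k$k1 / k$k2
  expect_gt(ratio, 10^2.5)   # roughly three orders of magnitude
  expect_lt(ratio, 10^3.6)

  expect_warning(carbonate_constants(25, 45), "validity")
  expect_silent(carbonate_constants(25, 45, quiet = TRUE))
})

test_that("missing nutrients are filled with defaults and flagged", {
  s <- tibble::tibble(po4_umol_l = c(NA, 1, 0.5), sioh4_umol_l = c(NA, NA, 80))
  f <- fill_missing_nutrients(s)
  expect_equal(f$po4_umol_l, c(2.84, 1, 0.5))
  expect_equal(f$sioh4_umol_l, c(141.91, 141.91, 80))
  expect_equal(f$po4_source, c("default", "measured", "measured"))
  expect_equal(f$si_source, c("default", "default", "measured"))

  # absent columns are created and fully filled
  f2 <- fill_missing_nutrients(tibble::tibble(x = 1:2), 3, 100)
  expect_equal(f2$po4_umol_l, c(3, 3))
  expect_equal(f2$sioh4_umol_l, c(100, 100))
})

test_that("speciation reproduces the input alkalinity to 0.01 umol/L", {
  g <- oracle_grid()
  r <- suppressWarnings(speciate(g[, 1:6]))
  k <- carbonate_constants(g$temp_c, g$salinity, quiet = TRUE)
  nc <- noncarbonate_alkalinity(10^(-g$ph_nbs), k, g$po4_umol_l, g$sioh4_umol_l)
  ta_back <- r$hco3_umol_l + 2 * r$co3_umol_l + nc$total_umol_l
  expect_lt(max(abs(ta_back - g$alk_umol_l)), 0.01)
  expect_equal(r$dic_umol_l, r$co2_star_umol_l + r$hco3_umol_l + r$co3_umol_l)
})

test_that("water pCO2 agrees with the independent oracle within 5% over the study grid", {
  g <- oracle_grid()
  r <- suppressWarnings(speciate(g[, 1:6]))
  rel <- abs(r$pco2_uatm - g$pco2_uatm) / g$pco2_uatm
  expect_lt(max(rel), 0.05)
})

test_that("pH at the in-situ pK1 splits CO2* and bicarbonate equally", {
  k <- carbonate_constants(20, 1, quiet = TRUE)
  s <- tibble::tibble(temp_c = 20, salinity = 1, ph_nbs = -log10(k$k1),
                      alk_umol_l = 3000, po4_umol_l = 2.84, sioh4_umol_l = 141.91)
  r <- speciate(s, constants = k)
  expect_equal(r$co2_star_umol_l, r$hco3_umol_l, tolerance = 1e-9)
})

test_that("pCO2 is linear in carbonate alkalinity and decreasing in pH", {
  base <- tibble::tibble(temp_c = 20, salinity = 0, ph_nbs = 8,
                         alk_umol_l = 3000, po4_umol_l = 0, sioh4_umol_l = 0)
  r1 <- speciate(base)
  r2 <- speciate(dplyr::mutate(base, alk_umol_l = 6000))
  # exactly proportional to carbonate alkalinity at fixed [H+] ...
  expect_equal(r2$pco2_uatm / r1$pco2_uatm,
               r2$carb_alk_umol_l / r1$carb_alk_umol_l, tolerance = 1e-12)
  # ... hence doubling TA (tiny non-carbonate terms here) ~doubles pCO2
  expect_equal(r2$pco2_uatm / r1$pco2_uatm, 2, tolerance = 0.01)

  phs <- seq(7, 10, by = 0.25)
  grid <- tibble::tibble(temp_c = 20, salinity = 1, ph_nbs = phs,
                         alk_umol_l = 3000, po4_umol_l = 2.84, sioh4_umol_l = 141.91)
  expect_true(all(diff(speciate(grid)$pco2_uatm) < 0))
})

test_that("non-carbonate alkalinity decomposes into its exposed terms", {
  k <- carbonate_constants(25, 0, quiet = TRUE)
  nc <- noncarbonate_alkalinity(1e-7, k, 0, 0)
  expect_lt(abs(nc$total_umol_l), 0.5)             # ~neutral fresh water
  expect_equal(nc$total_umol_l,
               nc$borate_umol_l + nc$hydroxide_minus_proton_umol_l +
                 nc$phosphate_umol_l + nc$silicate_umol_l)

  k35 <- carbonate_constants(25, 35)
  nc_hi <- noncarbonate_alkalinity(1e-10, k35, 1, 10)   # pH 10
  expect_gt(nc_hi$total_umol_l, 0)
  expect_gt(nc_hi$borate_umol_l + nc_hi$hydroxide_minus_proton_umol_l,
            0.8 * nc_hi$total_umol_l)
})

test_that("non-carbonate alkalinity exceeding TA is flagged, not NaN", {
  s <- tibble::tibble(temp_c = 20, salinity = 5, ph_nbs = 10,
                      alk_umol_l = 50, po4_umol_l = 5, sioh4_umol_l = 500)
  expect_warning(r <- speciate(s), "invalid")
  expect_false(r$speciation_ok)
  expect_true(is.na(r$pco2_uatm))
  expect_lt(r$carb_alk_umol_l, 0)   # diagnostics retained
})

test_that("ph_for_pco2 inverts speciation exactly", {
  targets <- c(20, 380, 2500, 9000)
  ph <- ph_for_pco2(targets, alk_umol_l = 3200, temp_c = 18, salinity = 0.8)
  s <- tibble::tibble(temp_c = 18, salinity = 0.8, ph_nbs = ph,
                      alk_umol_l = 3200, po4_umol_l = 2.84, sioh4_umol_l = 141.91)
  expect_equal(speciate(s)$pco2_uatm, targets, tolerance = 1e-6)
})
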