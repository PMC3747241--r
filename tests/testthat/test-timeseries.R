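mk_samples <- function(site, dates, pco2) {
  tibble::tibble(site_id = site, date = dates, temp_c = 20, salinity = 1,
                 pco2_uatm = pco2, alk_umol_l = 3000)
}

test_that("daily interpolation is exact at knots and linear between them", {
  s <- mk_samples("a", as.Date("2010-01-01") + c(0, 30), c(100, 400))
  d <- interpolate_daily(s)
  expect_equal(nrow(d), 31)
  expect_equal(d$pco2_uatm[d$date == as.Date("2010-01-16")], 250)   # day 15
  expect_equal(d$pco2_uatm[c(1, 31)], c(100, 400))                  # knots exact
  expect_equal(range(d$date), range(s$date))                        # no extrapolation
  expect_true(all(d$wet_flag))
})

test_that("declared dry gaps break interpolation into wet segments", {
  dates <- as.Date(c("2010-01-10", "2010-02-10", "2010-05-10", "2010-06-10"))
  s <- mk_samples("a", dates, c(100, 200, 1000, 2000))
  gaps <- tibble::tibble(site_id = "a", start = as.Date("2010-03-01"),
                         end = as.Date("2010-04-30"))
  d <- interpolate_daily(s, dry_gaps = gaps)
  in_gap <- d$date >= gaps$start & d$date <= gaps$end
  expect_true(all(!d$wet_flag[in_gap]))
  expect_true(all(is.na(d$pco2_uatm[in_gap])))
  # within-segment values never use the other segment's samples
  expect_equal(d$pco2_uatm[d$date == as.Date("2010-02-10")], 200)
  expect_true(all(is.na(d$pco2_uatm[d$date > as.Date("2010-02-10") &
                                      d$date < gaps$start])))
  expect_equal(d$pco2_uatm[d$date == as.Date("2010-05-10")], 1000)

  expect_error(
    interpolate_daily(mk_samples("a", as.Date("2010-03-15"), 500),
                      dry_gaps = tibble::tibble(site_id = "a",
                                                start = as.Date("2010-03-01"),
                                                end = as.Date("2010-03-31"))),
    "dry gap"
  )
})

test_that("a single sample degenerates to a one-day series with a warning", {
  expect_warning(d <- interpolate_daily(mk_samples("a", as.Date("2010-01-05"), 500)),
                 "single sample")
  expect_equal(nrow(d), 1)
  expect_equal(d$pco2_uatm, 500)
})

test_that("daily fluxes carry the sign of the pCO2 gradient and count wet days", {
  days <- as.Date("2010-03-01") + 0:30
  sd <- tibble::tibble(site_id = "a", date = days, wet_flag = TRUE,
                       temp_c = 20, salinity = 0, pco2_uatm = 1380,
                       alk_umol_l = 3000)
  met <- tibble::tibble(date = days, u10_m_s = 3, pco2_atm_uatm = 380)
  f <- daily_fluxes(sd, met)
  expect_equal(nrow(f), 31)
  expect_equal(length(unique(round(f$flux_mmol_m2_d, 12))), 1)   # constant in, constant out
  expect_true(all(f$flux_mmol_m2_d > 0))

  f_neg <- daily_fluxes(dplyr::mutate(sd, pco2_uatm = 100), met)
  expect_true(all(f_neg$flux_mmol_m2_d < 0))

  expect_message(
    f_gap <- daily_fluxes(sd, met[-(3:5), ]),
    "missing meteorology"
  )
  expect_equal(nrow(f_gap), 28)   # one record per wet day with meteorology
})

test_that("annual areal flux sums daily values and is split-invariant", {
  rec <- tibble::tibble(site_id = "a", date = as.Date("2010-03-01") + 0:364,
                        flux_mmol_m2_d = 10)
  expect_equal(annual_areal_flux(rec)$annual_flux_mol_m2_y, 3.65)
  expect_equal(annual_areal_flux(rec)$n_wet_days, 365L)

  empty <- rec[0, ]
  expect_equal(nrow(annual_areal_flux(empty)), 0)

  # splitting the year into segments and summing segment totals is identical
  rec2 <- dplyr::mutate(rec, flux_mmol_m2_d = sin(1:365) * 40)
  total <- annual_areal_flux(rec2)$annual_flux_mol_m2_y
  parts <- sum(annual_areal_flux(rec2[1:100, ])$annual_flux_mol_m2_y,
               annual_areal_flux(rec2[101:365, ])$annual_flux_mol_m2_y)
  expect_equal(total, parts, tolerance = 1e-12)

  expect_error(
    annual_areal_flux(tibble::tibble(site_id = "a",
                                     date = as.Date("2010-01-01") + seq(0, 500, 50),
                                     flux_mmol_m2_d = 1)),
    "more than one year"
  )
})

test_that("summary statistics use moment skewness and raw kurtosis", {
  s <- summary_stats(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$range, 4)
  expect_equal(s$iqr, 2)
  expect_equal(s$skewness, 0)

  set.seed(99)
  g <- summary_stats(rnorm(20000))
  expect_equal(g$skewness, 0, tolerance = 0.1)
  expect_equal(g$kurtosis, 3, tolerance = 0.15)   # raw, not excess

  const <- summary_stats(rep(2, 10))
  expect_equal(const$sd, 0)
  expect_false(const$moments_defined)
  expect_true(is.na(const$skewness))
  expect_false(summary_stats(5)$moments_defined)
})

test_that("monthly flux signs track the generator's pCO2 gradient pattern", {
  run <- fx_run()
  truth <- fx_truth()
  by_month <- function(df) {
    df$month <- format(df$date, "%Y-%m")
    dplyr::summarise(dplyr::group_by(df, site_id, month),
                     f = mean(flux_mmol_m2_d), .groups = "drop")
  }
  got <- by_month(run$flux_daily)
  want <- by_month(truth$site_daily)
  j <- dplyr::inner_join(got, want, by = c("site_id", "month"),
                         suffix = c("", "_true"))
  # compare signs away from the zero crossing
  strong <- abs(j$f_true) > 1
  expect_gt(sum(strong), 50)
  expect_true(all(sign(j$f[strong]) == sign(j$f_true[strong])))
})
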