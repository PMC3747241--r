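toy_scene <- function(nir, px = 30) reflectance_scene(nir, px, date = as.Date("2010-06-01"))

test_that("major-axis normalization recovers linear radiometric distortions", {
  set.seed(7)
  base <- matrix(runif(400, 0.05, 0.45), 20)
  ref <- toy_scene(base)
  pif <- cbind(row = c(2, 5, 9, 14, 18), col = c(3, 8, 11, 16, 19))

  # identical scenes: identity transform
  n0 <- normalize_scene(toy_scene(base), ref, pif)
  expect_equal(n0$normalization$slope, 1, tolerance = 1e-12)
  expect_equal(n0$normalization$intercept, 0, tolerance = 1e-12)
  expect_equal(n0$nir, base)

  # scene = 2 * reference exactly: slope 0.5 applied everywhere
  n2 <- normalize_scene(toy_scene(2 * base), ref, pif)
  expect_equal(n2$normalization$slope, 0.5, tolerance = 1e-12)

  expect_error(normalize_scene(toy_scene(matrix(0.3, 20, 20)), ref, pif), "variance")
  expect_error(normalize_scene(toy_scene(base), ref, pif[1:2, ]), ">= 3 PIF")
})

test_that("major-axis slope depends on the variance ratio, not the OLS fit", {
  # hand-built 5-point set: var(x) = 4 var(y), imperfect correlation
  x <- c(0.2, 0.6, 0.4, 1.0, 0.8)
  y <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  scn <- toy_scene(matrix(x, 1)); ref <- toy_scene(matrix(y, 1))
  pif <- cbind(rep(1, 5), 1:5)
  n <- normalize_scene(scn, ref, pif)
  expect_equal(abs(n$normalization$slope), 0.5, tolerance = 1e-12)
  ols <- stats::cov(x, y) / stats::var(x)
  expect_false(isTRUE(all.equal(abs(n$normalization$slope), ols)))
})

test_that("water classification is a strict NIR threshold excluding nodata", {
  m <- matrix(0, 4, 4)
  expect_true(all(classify_water(toy_scene(m))))

  m2 <- matrix(c(0.1, 0.2, 0.25, NA), 2)
  w <- classify_water(toy_scene(m2))
  expect_identical(as.vector(w), c(TRUE, FALSE, FALSE, NA))   # 0.2 is not water
})

test_that("region water area counts pixel centers inside the polygon", {
  # 20 x 20 raster at 30 m; water = a 10 x 10 block (rows/cols 1-10)
  m <- matrix(0.5, 20, 20)
  m[1:10, 1:10] <- 0.05
  scn <- toy_scene(m, 30)
  mask <- classify_water(scn)
  all_poly <- data.frame(x = c(0, 600, 600, 0), y = c(0, 0, 600, 600))
  expect_equal(region_water_area(mask, scn, all_poly), 100 * 900 / 1e6)   # 0.09 km2

  # polygon covering only a 5 x 5 corner of the water block
  sub <- data.frame(x = c(0, 150, 150, 0), y = c(0, 0, 150, 150))
  expect_equal(region_water_area(mask, scn, sub), 25 * 900 / 1e6)

  expect_equal(region_water_area(classify_water(toy_scene(matrix(0.5, 20, 20))),
                                 scn, all_poly), 0)
  expect_warning(
    a <- region_water_area(mask, scn, data.frame(x = c(1e6, 1e6 + 10, 1e6 + 10),
                                                 y = c(0, 0, 10))),
    "does not intersect"
  )
  expect_equal(a, 0)
})

test_that("scene-date areas interpolate linearly to daily series", {
  a <- tibble::tibble(date = as.Date("2010-01-01") + c(0, 30),
                      area_km2 = c(10, 40))
  d <- interpolate_area_daily(a)
  expect_equal(d$area_km2[d$date == as.Date("2010-01-16")], 25)
  expect_equal(d$area_km2[c(1, 31)], c(10, 40))
  expect_true(all(d$area_km2 >= 0))
  expect_warning(interpolate_area_daily(a[1, ]), "single scene")
})

test_that("regional transport converts mean areal flux times area to grams of C", {
  day <- as.Date("2010-06-01")
  fx <- tibble::tibble(site_id = "a", date = day, flux_mmol_m2_d = 10)
  rs <- tibble::tibble(region_id = "r", site_id = "a")
  ar <- tibble::tibble(region_id = "r", date = day, area_km2 = 1)
  tr <- regional_daily_transport(fx, rs, ar)
  expect_equal(tr$transport_g_c_d, 120110)   # 10^4 mol C = 120.11 kg C

  expect_equal(regional_daily_transport(fx, rs,
                                        dplyr::mutate(ar, area_km2 = 0))$transport_g_c_d, 0)

  fx2 <- tibble::tibble(site_id = c("a", "b"), date = day,
                        flux_mmol_m2_d = c(10, -10))
  rs2 <- tibble::tibble(region_id = "r", site_id = c("a", "b"))
  expect_equal(regional_daily_transport(fx2, rs2, ar)$transport_g_c_d, 0)

  expect_message(
    dry <- regional_daily_transport(fx[0, ], rs, ar),
    "no wet site"
  )
  expect_equal(dry$transport_g_c_d, 0)
})

test_that("transport is linear in area and in the site mean (superposition)", {
  set.seed(11)
  day <- as.Date("2010-06-01")
  sites <- paste0("s", 1:6)
  fx <- tibble::tibble(site_id = sites, date = day,
                       flux_mmol_m2_d = rnorm(6, 20, 15))
  ar <- tibble::tibble(region_id = "r", date = day, area_km2 = 3.7)
  whole <- regional_daily_transport(
    fx, tibble::tibble(region_id = "r", site_id = sites), ar)$transport_g_c_d
  for (k in 1:3) {
    pick <- sample(sites, 3)
    t1 <- regional_daily_transport(
      fx, tibble::tibble(region_id = "r", site_id = pick), ar)$transport_g_c_d
    t2 <- regional_daily_transport(
      fx, tibble::tibble(region_id = "r", site_id = setdiff(sites, pick)), ar)$transport_g_c_d
    expect_equal((t1 + t2) / 2, whole, tolerance = 1e-12)
  }
  # doubling area doubles transport
  whole2 <- regional_daily_transport(
    fx, tibble::tibble(region_id = "r", site_id = sites),
    dplyr::mutate(ar, area_km2 = 7.4))$transport_g_c_d
  expect_equal(whole2, 2 * whole, tolerance = 1e-12)
})

test_that("annual transport sums grams to Gg and propagates sign", {
  expect_equal(annual_transport(rep(1e5, 365)), 0.0365)
  expect_lt(annual_transport(c(rep(1e5, 100), rep(-2e5, 100))), 0)
  expect_error(annual_transport(rep(1, 400)), "366")
})

test_that("the NPP comparison converts moles to Gg C and guards the ratio", {
  n <- npp_comparison(27, 231, 13.1)
  expect_equal(n$npp_gg_c_y, 27 * 12.011 * 231 * 1e6 / 1e9, tolerance = 1e-12)
  expect_equal(round(n$npp_gg_c_y), 75)
  expect_equal(n$ratio, n$npp_gg_c_y / 13.1)

  expect_equal(npp_comparison(27, 462, 13.1)$npp_gg_c_y, 2 * n$npp_gg_c_y)

  bad <- npp_comparison(27, 231, -1)
  expect_false(bad$ratio_defined)
  expect_true(is.na(bad$ratio))
})

test_that("normalization is idempotent for classification when PIFs already match", {
  set.seed(5)
  base <- matrix(runif(900, 0, 0.7), 30)
  scn <- toy_scene(base)
  pif <- cbind(sample(30, 8), sample(30, 8))
  norm <- normalize_scene(scn, scn, pif)
  expect_equal(classify_water(norm), classify_water(scn))
})

test_that("single-band TIFF scenes round-trip through the reader", {
  set.seed(3)
  m <- matrix(round(runif(100), 3), 10)
  path <- tempfile(fileext = ".tif")
  tiff::writeTIFF(m, path, bits.per.sample = 32L)
  scn <- read_scene_tiff(path, 30, date = as.Date("2010-06-01"))
  expect_s3_class(scn, "reflectance_scene")
  expect_equal(scn$nir, m, tolerance = 1e-6)
  unlink(path)
})
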