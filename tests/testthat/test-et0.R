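test_that("saturation vapour pressure matches hand-derived values and is increasing", {
  expect_equal(saturation_vapor_pressure(0), 0.6108)
  expect_equal(saturation_vapor_pressure(20), 2.338, tolerance = 1e-3)
  expect_equal(saturation_vapor_pressure(30), 4.243, tolerance = 1e-3)
  t <- seq(-20, 50, by = 0.5)
  expect_true(all(diff(saturation_vapor_pressure(t)) > 0))
  expect_error(saturation_vapor_pressure(NaN), class = "warabandi_invalid_input")
})

test_that("daily mean e_s averages the curve at the extremes", {
  expect_equal(mean_saturation_vapor_pressure(20, 20),
               saturation_vapor_pressure(20))
  expect_equal(mean_saturation_vapor_pressure(30, 20), 3.290,
               tolerance = 2e-3 / 3.290)
  expect_equal(mean_saturation_vapor_pressure(0, 0), 0.6108)
  expect_error(mean_saturation_vapor_pressure(10, 20),
               class = "warabandi_invalid_input")
})

test_that("actual vapour pressure honours both pairings and the e_a <= e_s bound", {
  # saturated and bone-dry boundary cases
  expect_equal(actual_vapor_pressure(30, 20, 100, 100),
               mean_saturation_vapor_pressure(30, 20))
  expect_equal(actual_vapor_pressure(30, 20, 0, 0), 0)
  # literal pairing weights e0(Tmax) by RHmax
  expect_equal(actual_vapor_pressure(30, 20, 80, 40, pairing = "literal"),
               2.165, tolerance = 3e-3 / 2.165)
  # FAO pairing keeps e_a below e_s on random days
  d <- random_weather_days(50, seed = 11)
  ea <- actual_vapor_pressure(d$t_max, d$t_min, d$rh_max, d$rh_min)
  es <- mean_saturation_vapor_pressure(d$t_max, d$t_min)
  expect_true(all(ea <= es + 1e-9))
  expect_error(actual_vapor_pressure(30, 20, 120, 40),
               class = "warabandi_invalid_input")
})

test_that("slope of the saturation curve uses the 0.6108 coefficient", {
  expect_equal(vapor_pressure_slope(25), 0.189, tolerance = 1e-3 / 0.189)
  expect_equal(vapor_pressure_slope(0), 0.0445, tolerance = 1e-3 / 0.0445)
  expect_gt(vapor_pressure_slope(30), vapor_pressure_slope(20))
})

test_that("pressure profile and psychrometric constant agree with hand values", {
  expect_equal(atmospheric_pressure(0), 101.3)
  expect_equal(atmospheric_pressure(100), 100.1, tolerance = 0.05 / 100.1)
  expect_equal(atmospheric_pressure(2000), 79.84, tolerance = 0.1 / 79.84)
  expect_true(all(diff(atmospheric_pressure(seq(0, 3000, 100))) < 0))
  expect_equal(psychrometric_constant(101.3), 0.0674,
               tolerance = 2e-4 / 0.0674)
  expect_equal(psychrometric_constant(79.84), 0.0531,
               tolerance = 2e-4 / 0.0531)
  expect_error(atmospheric_pressure(-500), class = "warabandi_invalid_input")
})

test_that("wind rescaling follows the log profile", {
  expect_equal(wind_to_2m(0, 10), 0)
  expect_equal(wind_to_2m(1, 10), 0.748, tolerance = 1e-3 / 0.748)
  expect_equal(wind_to_2m(3, 2), 3.0006, tolerance = 2e-3 / 3)
  expect_error(wind_to_2m(1, 0.05), class = "warabandi_invalid_input")
})

test_that("extraterrestrial radiation matches the reference solar geometry", {
  # polar night: clamped sunset angle gives exactly zero
  expect_equal(extraterrestrial_radiation(70, 355), 0)
  # equator at the equinox and the trial latitude in late May
  expect_equal(extraterrestrial_radiation(0, 81), 37.804, tolerance = 0.1 / 37.8)
  expect_equal(extraterrestrial_radiation(24.9, 150), 40.268,
               tolerance = 0.1 / 40.3)
  expect_true(all(extraterrestrial_radiation(seq(-90, 90, 15), 100) >= 0))
})

test_that("net radiation handles zero temperature range and polar night", {
  r0 <- net_radiation(20, 20, 1.5, 45, 100, 180)
  expect_equal(r0$r_s, 0)
  expect_equal(r0$r_ns, 0)
  rp <- net_radiation(-20, -30, 0.1, 70, 0, 355)
  expect_equal(rp$r_a, 0)
  expect_equal(rp$r_s, 0)
  expect_equal(rp$r_ns, 0)
  expect_equal(rp$r_nl, 0)
  # a hot coastal-plain day against the straight-line reference chain
  rk <- net_radiation(34, 26, 2.674391, 24.9, 20, 150)
  expect_equal(rk$r_n, 11.895, tolerance = 0.2 / 11.9)
  expect_true(all(rk$r_s <= rk$r_so + 1e-12))
  expect_error(net_radiation(20, 25, 1, 45, 0, 100),
               class = "warabandi_invalid_input")
})

test_that("calc_et0 populates consistent sub-terms and reproduces the combination equation", {
  w <- tibble::tibble(date = as.Date("2018-05-30"), t_max = 34, t_min = 26,
                      rh_max = 80, rh_min = 50, wind_speed = 4)
  site <- site_geometry(24.9, 67.3, elevation_z = 20)
  r <- calc_et0(w, site)
  expect_equal(r$soil_heat_flux_g, 0)
  expect_equal(r$r_n, r$r_ns - r$r_nl)
  expect_lte(r$e_a, r$e_s + 1e-9)
  # recomposing the equation from the returned sub-terms is exact
  tmean <- (w$t_max + w$t_min) / 2
  recomposed <- (0.408 * r$delta * (r$r_n - r$soil_heat_flux_g) +
                   r$gamma * 900 / (tmean + 273) * r$u2 * (r$e_s - r$e_a)) /
    (r$delta + r$gamma * (1 + 0.34 * r$u2))
  expect_identical(r$et0, max(recomposed, 0))
  expect_equal(r$et0, 5.7426, tolerance = 0.05 / 5.74)
})

test_that("ET0 equals an independent FAO-56 reference on 200 random days", {
  d <- random_weather_days(200, seed = 42)
  site <- site_geometry(24.9, 67.3, elevation_z = 20)
  got <- calc_et0(d, site)$et0
  want <- mapply(fao56_reference_et0, d$t_max, d$t_min, d$rh_max, d$rh_min,
                 d$wind_speed, MoreArgs = list(lat_deg = 24.9, elev = 20),
                 doy = as.integer(format(d$date, "%j")))
  expect_lt(max(abs(got - want)), 0.05)
})

test_that("ET0 is monotone in vapour-pressure deficit and net radiation", {
  base <- tibble::tibble(date = as.Date("2018-06-15"), t_max = 38,
                         t_min = 26, rh_max = 70, rh_min = 40,
                         wind_speed = 3)
  site <- site_geometry(24.9, 67.3, 20)
  drier <- dplyr::mutate(base, rh_max = 40, rh_min = 15)   # larger deficit
  expect_gt(calc_et0(drier, site)$et0, calc_et0(base, site)$et0)
  sunnier <- calc_et0(base, site, k_rs = 0.19)             # more shortwave
  expect_gt(sunnier$et0, calc_et0(base, site)$et0)
})

test_that("mean-RH fallback estimates e_a as RHmean/100 * e_s", {
  w <- tibble::tibble(date = as.Date("2018-05-30"), t_max = 34, t_min = 26,
                      rh_mean = 60, wind_speed = 4)
  site <- site_geometry(24.9, 67.3, 20)
  expect_message(r <- calc_et0(w, site), "mean RH")
  expect_equal(r$e_a, 0.6 * mean_saturation_vapor_pressure(34, 26))
})

test_that("weather validation enforces the physical invariants", {
  ok <- random_weather_days(5, seed = 2)
  expect_s3_class(validate_daily_weather(ok), "tbl_df")
  bad_t <- dplyr::mutate(ok, t_min = t_max + 1)
  expect_error(validate_daily_weather(bad_t), class = "warabandi_invalid_input")
  bad_rh <- dplyr::mutate(ok, rh_min = rh_max + 5)
  expect_error(validate_daily_weather(bad_rh), class = "warabandi_invalid_input")
  expect_error(validate_daily_weather(ok[, -1]), class = "warabandi_invalid_input")
})
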