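#' Describe a monitored site
#'
#' Bundles the geometry the reference-evapotranspiration chain needs: where
#' the field is (latitude drives extraterrestrial radiation, elevation drives
#' atmospheric pressure and the clear-sky envelope) and how high above ground
#' the wind record was taken (third-party wind products are typically
#' reported at 10 m and must be rescaled to the 2 m FAO reference level).
#'
#' @param latitude Decimal degrees, positive north. Must lie in \[-90, 90\].
#' @param longitude Decimal degrees (informational only; daily radiation
#'   totals depend on latitude alone).
#' @param elevation_z Metres above sea level; must be >= -430 (the lowest
#'   land surface on Earth).
#' @param anemometer_height Height of the wind measurement above ground,
#'   metres. Defaults to 10, the standard meteorological mast height.
#' @return A list of class `site_geometry`.
#' @examples
#' gadap <- site_geometry(24.9, 67.3, elevation_z = 20)
#' @export
site_geometry <- function(latitude, longitude = NA_real_, elevation_z = 0,
                          anemometer_height = 10) {
  check_finite_numeric(latitude, "latitude")
  check_finite_numeric(elevation_z, "elevation_z")
  check_finite_numeric(anemometer_height, "anemometer_height")
  if (latitude < -90 || latitude > 90) {
    abort_input("`latitude` must lie in [-90, 90] degrees.")
  }
  if (elevation_z < -430) abort_input("`elevation_z` must be >= -430 m.")
  if (anemometer_height <= 5.42 / 67.8) {
    abort_input("`anemometer_height` must exceed 0.08 m for the log wind profile.")
  }
  structure(
    list(latitude = latitude, longitude = longitude,
         elevation_z = elevation_z, anemometer_height = anemometer_height),
    class = "site_geometry"
  )
}

#' Saturation vapour pressure at an air temperature
#'
#' Tetens-type exponential used throughout the FAO-56 chain:
#' e0(T) = 0.6108 exp\[17.27 T / (T + 237.3)\].
#'
#' @param t Air temperature, degrees Celsius. Vectorised.
#' @return Saturation vapour pressure, kPa.
#' @examples
#' saturation_vapor_pressure(20) # 2.338 kPa
#' @export
saturation_vapor_pressure <- function(t) {
  check_finite_numeric(t, "t")
  if (any(t <= -237.3)) abort_input("`t` must exceed -237.3 degC.")
  0.6108 * exp(17.27 * t / (t + 237.3))
}

#' Daily mean saturation vapour pressure
#'
#' The daily e_s is the mean of the saturation curve evaluated at the daily
#' extremes, not the curve at the mean temperature: the curve is convex, so
#' using the mean temperature would understate the day's drying power.
#'
#' @param t_max,t_min Daily maximum and minimum air temperature, degC.
#' @return Mean saturation vapour pressure e_s, kPa.
#' @export
mean_saturation_vapor_pressure <- function(t_max, t_min) {
  check_finite_numeric(t_max, "t_max")
  check_finite_numeric(t_min, "t_min")
  if (any(t_max < t_min)) abort_input("`t_max` must be >= `t_min`.")
  (saturation_vapor_pressure(t_max) + saturation_vapor_pressure(t_min)) / 2
}

#' Actual vapour pressure from daily RH extremes
#'
#' Default pairing follows FAO-56: RH is highest around dawn when the air is
#' coolest and lowest in mid-afternoon when it is warmest, so RHmax pairs
#' with e0(Tmin) and RHmin with e0(Tmax). That pairing guarantees
#' e_a <= e_s. `pairing = "literal"` instead multiplies RHmax by e0(Tmax)
#' and RHmin by e0(Tmin), which can exceed e_s on dry days.
#'
#' @param t_max,t_min Daily temperature extremes, degC.
#' @param rh_max,rh_min Daily relative-humidity extremes, percent in \[0, 100\].
#' @param pairing `"fao"` (default) or `"literal"`.
#' @return Actual vapour pressure e_a, kPa.
#' @export
actual_vapor_pressure <- function(t_max, t_min, rh_max, rh_min,
                                  pairing = c("fao", "literal")) {
  pairing <- match.arg(pairing)
  check_finite_numeric(rh_max, "rh_max")
  check_finite_numeric(rh_min, "rh_min")
  if (any(rh_max < 0 | rh_max > 100 | rh_min < 0 | rh_min > 100)) {
    abort_input("relative humidity must lie in [0, 100] percent.")
  }
  e_tmax <- saturation_vapor_pressure(t_max)
  e_tmin <- saturation_vapor_pressure(t_min)
  if (pairing == "fao") {
    (e_tmin * rh_max / 100 + e_tmax * rh_min / 100) / 2
  } else {
    (e_tmax * rh_max / 100 + e_tmin * rh_min / 100) / 2
  }
}

#' Actual vapour pressure from mean relative humidity
#'
#' Fallback when only a daily mean RH is available: e_a = RHmean/100 * e_s.
#'
#' @param t_max,t_min Daily temperature extremes, degC.
#' @param rh_mean Daily mean relative humidity, percent.
#' @return e_a, kPa.
#' @export
actual_vapor_pressure_rhmean <- function(t_max, t_min, rh_mean) {
  check_finite_numeric(rh_mean, "rh_mean")
  if (any(rh_mean < 0 | rh_mean > 100)) {
    abort_input("`rh_mean` must lie in [0, 100] percent.")
  }
  rh_mean / 100 * mean_saturation_vapor_pressure(t_max, t_min)
}

#' Slope of the saturation vapour-pressure curve
#'
#' Delta(T) = 4098 e0(T) / (T + 237.3)^2, kPa per degC, evaluated at the
#' daily mean temperature in the combination equation. The Tetens
#' coefficient is 0.6108, consistent with [saturation_vapor_pressure()].
#'
#' @param t Air temperature, degC.
#' @return Slope, kPa/degC.
#' @export
vapor_pressure_slope <- function(t) {
  check_finite_numeric(t, "t")
  if (any(t <= -237.3)) abort_input("`t` must exceed -237.3 degC.")
  4098 * (0.6108 * exp(17.27 * t / (t + 237.3))) / (t + 237.3)^2
}

#' Atmospheric pressure from elevation
#'
#' Standard-atmosphere profile P = 101.3 ((293 - 0.0065 z) / 293)^5.26, kPa.
#'
#' @param elevation_z Metres above sea level, >= -430.
#' @return Pressure, kPa.
#' @export
atmospheric_pressure <- function(elevation_z) {
  check_finite_numeric(elevation_z, "elevation_z")
  if (any(elevation_z < -430)) abort_input("`elevation_z` must be >= -430 m.")
  101.3 * ((293 - 0.0065 * elevation_z) / 293)^5.26
}

#' Psychrometric constant
#'
#' gamma = 0.665e-3 P with P in kPa, giving about 0.0674 kPa/degC at sea
#' level.
#'
#' @param pressure_P Atmospheric pressure, kPa, > 0.
#' @return gamma, kPa/degC.
#' @export
psychrometric_constant <- function(pressure_P) {
  check_finite_numeric(pressure_P, "pressure_P")
  if (any(pressure_P <= 0)) abort_input("`pressure_P` must be positive.")
  0.665e-3 * pressure_P
}

#' Rescale wind speed to the 2 m reference level
#'
#' Logarithmic profile over short grass:
#' u2 = u_z * 4.87 / ln(67.8 z - 5.42), with z the measurement height above
#' ground in metres. At z = 2 the factor is 1 to within 1e-3.
#'
#' @param u_z Wind speed at `measurement_height`, m/s, >= 0.
#' @param measurement_height Height above ground, metres, > 0.08.
#' @return Wind speed at 2 m, m/s.
#' @export
wind_to_2m <- function(u_z, measurement_height) {
  check_finite_numeric(u_z, "u_z")
  check_finite_numeric(measurement_height, "measurement_height")
  if (any(u_z < 0)) abort_input("`u_z` must be >= 0.")
  if (any(measurement_height <= 5.42 / 67.8)) {
    abort_input("`measurement_height` must exceed 0.08 m.")
  }
  u_z * 4.87 / log(67.8 * measurement_height - 5.42)
}

#' Daily extraterrestrial radiation
#'
#' Top-of-atmosphere solar radiation R_a from latitude and day of year via
#' the solar geometry chain (inverse relative Earth-Sun distance, solar
#' declination, sunset hour angle). The cosine argument of the sunset hour
#' angle is clamped to \[-1, 1\], so polar night yields exactly 0 and polar
#' day a full-circle integral.
#'
#' @param latitude Decimal degrees in \[-90, 90\].
#' @param day_of_year Integer day of year, 1-366. Vectorised with recycling.
#' @return R_a, MJ m-2 day-1.
#' @export
extraterrestrial_radiation <- function(latitude, day_of_year) {
  check_finite_numeric(latitude, "latitude")
  check_finite_numeric(day_of_year, "day_of_year")
  if (any(latitude < -90 | latitude > 90)) {
    abort_input("`latitude` must lie in [-90, 90] degrees.")
  }
  if (any(day_of_year < 1 | day_of_year > 366)) {
    abort_input("`day_of_year` must lie in [1, 366].")
  }
  phi <- latitude * pi / 180
  j <- day_of_year
  dr <- 1 + 0.033 * cos(2 * pi * j / 365)
  decl <- 0.409 * sin(2 * pi * j / 365 - 1.39)
  cos_ws <- pmin(1, pmax(-1, -tan(phi) * tan(decl)))
  ws <- acos(cos_ws)
  ra <- (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
  pmax(ra, 0)
}

#' Net radiation at the grass reference surface
#'
#' Radiation budget estimated from the daily temperature range when no
#' pyranometer record exists:
#' * solar radiation `R_s = k_rs * sqrt(Tmax - Tmin) * R_a` (Hargreaves),
#' * clear-sky envelope `R_so = (0.75 + 2e-5 z) * R_a`,
#' * shortwave net `R_ns = (1 - albedo) * R_s`,
#' * longwave loss `R_nl` from the Stefan-Boltzmann law with vapour-pressure
#'   and cloudiness corrections, the relative shortwave ratio `R_s/R_so`
#'   clipped to \[0.25, 1\] so the cloudiness factor stays bounded and finite
#'   when `R_a = 0` (polar night, where `R_nl` is set to 0).
#'
#' @param t_max,t_min Daily temperature extremes, degC.
#' @param e_a Actual vapour pressure, kPa.
#' @param latitude Decimal degrees.
#' @param elevation_z Metres above sea level.
#' @param day_of_year Day of year 1-366.
#' @param k_rs Hargreaves adjustment coefficient, sqrt(degC)^-1; 0.16 for
#'   interior sites, ~0.19 for coastal.
#' @param albedo Grass reference albedo, default 0.23.
#' @return A tibble with columns `r_a`, `r_s`, `r_so`, `r_ns`, `r_nl`, `r_n`
#'   (all MJ m-2 day-1).
#' @export
net_radiation <- function(t_max, t_min, e_a, latitude, elevation_z,
                          day_of_year, k_rs = 0.16, albedo = 0.23) {
  check_finite_numeric(t_max, "t_max")
  check_finite_numeric(t_min, "t_min")
  check_finite_numeric(e_a, "e_a")
  if (any(t_max < t_min)) abort_input("`t_max` must be >= `t_min`.")
  r_a <- extraterrestrial_radiation(latitude, day_of_year)
  r_s <- k_rs * sqrt(pmax(t_max - t_min, 0)) * r_a
  r_so <- (0.75 + 2e-5 * elevation_z) * r_a
  ratio <- ifelse(r_so > 0, pmin(pmax(r_s / r_so, 0.25), 1), 0.25)
  sigma <- 4.903e-9 # MJ K-4 m-2 day-1
  tk4 <- ((t_max + 273.16)^4 + (t_min + 273.16)^4) / 2
  r_nl <- sigma * tk4 * (0.34 - 0.14 * sqrt(pmax(e_a, 0))) *
    (1.35 * ratio - 0.35)
  r_nl <- ifelse(r_so > 0, r_nl, 0)
  r_ns <- (1 - albedo) * r_s
  tibble(r_a = r_a, r_s = r_s, r_so = r_so, r_ns = r_ns, r_nl = r_nl,
         r_n = r_ns - r_nl)
}

#' Daily FAO-56 Penman-Monteith reference evapotranspiration
#'
#' Computes grass reference evapotranspiration for each row of a daily
#' weather table, returning every atmospheric sub-term alongside `et0` so
#' the combination equation can be audited term by term:
#'
#' \deqn{ET_0 = \frac{0.408\,\Delta\,(R_n - G) +
#'   \gamma\,\frac{900}{T+273}\,u_2\,(e_s - e_a)}
#'   {\Delta + \gamma\,(1 + 0.34\,u_2)}}
#'
#' Daily mean temperature is (t_max + t_min)/2; soil heat flux G is 0 at the
#' daily step; net radiation comes from [net_radiation()]. Negative raw
#' values (possible on cold overcast days when longwave loss exceeds the
#' radiative and aerodynamic supply) are floored at 0.
#'
#' @param weather Data frame with columns `date`, `t_max`, `t_min`,
#'   `rh_max`, `rh_min`, `wind_speed` (m/s at the site anemometer height).
#'   A `rh_mean` column may replace `rh_max`/`rh_min`, in which case the
#'   mean-RH fallback for e_a is used (a message notes this).
#' @param site A [site_geometry()].
#' @param ea_pairing Passed to [actual_vapor_pressure()].
#' @param k_rs,albedo Passed to [net_radiation()].
#' @return The input tibble with columns `e0_tmax`, `e0_tmin`, `e_s`, `e_a`,
#'   `delta`, `pressure_p`, `gamma`, `u2`, `r_a`, `r_s`, `r_so`, `r_ns`,
#'   `r_nl`, `r_n`, `soil_heat_flux_g` (always 0) and `et0` (mm/day)
#'   appended.
#' @examples
#' w <- tibble::tibble(date = as.Date("2018-05-30"), t_max = 34, t_min = 26,
#'                     rh_max = 80, rh_min = 50, wind_speed = 4)
#' calc_et0(w, site_geometry(24.9, 67.3, 20))$et0
#' @export
calc_et0 <- function(weather, site, ea_pairing = c("fao", "literal"),
                     k_rs = 0.16, albedo = 0.23) {
  ea_pairing <- match.arg(ea_pairing)
  stopifnot(inherits(site, "site_geometry"))
  weather <- validate_daily_weather(weather, require_rh_extremes = FALSE)
  doy <- as.integer(format(weather$date, "%j"))
  t_mean <- (weather$t_max + weather$t_min) / 2

  e0_tmax <- saturation_vapor_pressure(weather$t_max)
  e0_tmin <- saturation_vapor_pressure(weather$t_min)
  e_s <- (e0_tmax + e0_tmin) / 2
  if (all(c("rh_max", "rh_min") %in% names(weather))) {
    e_a <- actual_vapor_pressure(weather$t_max, weather$t_min,
                                 weather$rh_max, weather$rh_min,
                                 pairing = ea_pairing)
  } else {
    message("rh_max/rh_min absent: estimating e_a from mean RH (e_a = RHmean/100 * e_s).")
    e_a <- actual_vapor_pressure_rhmean(weather$t_max, weather$t_min,
                                        weather$rh_mean)
  }

  delta <- vapor_pressure_slope(t_mean)
  pressure_p <- atmospheric_pressure(site$elevation_z)
  gamma <- psychrometric_constant(pressure_p)
  u2 <- wind_to_2m(weather$wind_speed, site$anemometer_height)
  rad <- net_radiation(weather$t_max, weather$t_min, e_a,
                       site$latitude, site$elevation_z, doy,
                       k_rs = k_rs, albedo = albedo)
  g <- 0
  num <- 0.408 * delta * (rad$r_n - g) +
    gamma * 900 / (t_mean + 273) * u2 * (e_s - e_a)
  den <- delta + gamma * (1 + 0.34 * u2)
  et0 <- pmax(num / den, 0)

  dplyr::bind_cols(
    as_tibble(weather),
    tibble(e0_tmax = e0_tmax, e0_tmin = e0_tmin, e_s = e_s, e_a = e_a,
           delta = delta, pressure_p = pressure_p, gamma = gamma, u2 = u2),
    rad,
    tibble(soil_heat_flux_g = g, et0 = et0)
  )
}

#' Validate a daily weather table
#'
#' Checks column presence and the physical invariants (t_max >= t_min, RH in
#' \[0, 100\] with rh_max >= rh_min, wind >= 0) and returns the table with
#' `date` coerced to `Date`.
#'
#' @param weather Data frame of daily records.
#' @param require_rh_extremes If `FALSE`, a `rh_mean` column may stand in
#'   for `rh_max`/`rh_min`.
#' @return The validated tibble.
#' @export
validate_daily_weather <- function(weather, require_rh_extremes = TRUE) {
  needed <- c("date", "t_max", "t_min", "wind_speed")
  missing <- setdiff(needed, names(weather))
  if (length(missing)) {
    abort_input(paste0("weather table lacks column(s): ",
                       paste(missing, collapse = ", ")))
  }
  has_ext <- all(c("rh_max", "rh_min") %in% names(weather))
  if (!has_ext && (require_rh_extremes || !"rh_mean" %in% names(weather))) {
    abort_input("weather table needs rh_max/rh_min (or rh_mean) columns.")
  }
  weather <- as_tibble(weather)
  weather$date <- as_date_strict(weather$date)
  check_finite_numeric(weather$t_max, "t_max")
  check_finite_numeric(weather$t_min, "t_min")
  check_finite_numeric(weather$wind_speed, "wind_speed")
  if (any(weather$t_max < weather$t_min)) {
    abort_input("`t_max` must be >= `t_min` on every day.")
  }
  if (any(weather$wind_speed < 0)) abort_input("`wind_speed` must be >= 0.")
  if (has_ext) {
    rh <- c(weather$rh_max, weather$rh_min)
    if (any(rh < 0 | rh > 100)) abort_input("RH must lie in [0, 100].")
    if (any(weather$rh_max < weather$rh_min)) {
      abort_input("`rh_max` must be >= `rh_min` on every day.")
    }
  }
  weather
}
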