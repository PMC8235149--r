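# Independent FAO-56 daily Penman-Monteith reference implementation used as
# the oracle for the packaged chain. Deliberately a single straight-line
# transcription of the published equations, sharing no code with the
# package. Conventions: e_a from the RHmax/Tmin-RHmin/Tmax pairing, net
# radiation from the temperature-range (Hargreaves) shortwave estimate with
# k_Rs = 0.16 and albedo 0.23, G = 0, T = (Tmax + Tmin)/2.
fao56_reference_et0 <- function(tmax, tmin, rhmax, rhmin, u_wind, lat_deg,
                                elev, doy, anem_height = 10) {
  e0 <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  tmean <- (tmax + tmin) / 2
  es <- (e0(tmax) + e0(tmin)) / 2
  ea <- (e0(tmin) * rhmax / 100 + e0(tmax) * rhmin / 100) / 2
  delta <- 4098 * e0(tmean) / (tmean + 237.3)^2
  p <- 101.3 * ((293 - 0.0065 * elev) / 293)^5.26
  gam <- 0.665e-3 * p
  u2 <- u_wind * 4.87 / log(67.8 * anem_height - 5.42)

  phi <- lat_deg * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  dec <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- max(-1, min(1, -tan(phi) * tan(dec)))
  ws <- acos(x)
  ra <- 24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
  ra <- max(ra, 0)
  rs <- 0.16 * sqrt(max(tmax - tmin, 0)) * ra
  rso <- (0.75 + 2e-5 * elev) * ra
  ratio <- if (rso > 0) max(0.25, min(rs / rso, 1)) else 0.25
  rnl <- 4.903e-9 * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(ea)) * (1.35 * ratio - 0.35)
  if (rso <= 0) rnl <- 0
  rn <- (1 - 0.23) * rs - rnl

  num <- 0.408 * delta * rn + gam * 900 / (tmean + 273) * u2 * (es - ea)
  den <- delta + gam * (1 + 0.34 * u2)
  max(num / den, 0)
}

# Random physically plausible hot-climate days for oracle sweeps.
random_weather_days <- function(n, seed) {
  set.seed(seed)
  tmin <- runif(n, 5, 38)
  tmax <- tmin + runif(n, 2, 14)
  rhmin <- runif(n, 10, 70)
  rhmax <- pmin(rhmin + runif(n, 5, 30), 100)
  tibble::tibble(
    date = as.Date("2018-01-01") + sample.int(365, n, replace = TRUE) - 1,
    t_max = tmax, t_min = tmin, rh_max = rhmax, rh_min = rhmin,
    wind_speed = runif(n, 0, 10)
  )
}

default_setup <- function(seed = 1L) {
  spec <- karachi_season_spec(random_seed = seed)
  list(
    spec = spec,
    site = site_geometry(24.9, 67.3, elevation_z = 20),
    crop = lemon_profile(spec$start_date),
    soil = soil_profile(0.32, 0.12),
    calendar = warabandi_calendar(spec$start_date + 1), # weekly Friday turns
    flow = flow_spec(200)
  )
}
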