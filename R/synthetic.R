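#' Specify a synthetic weather season
#'
#' Parameters of the seeded generator: a sinusoidal annual cycle in daily
#' mean temperature (peaking in mid June, day of year 166), a fixed diurnal
#' range split evenly around the mean, an RH level anti-correlated with the
#' seasonal cycle, and independent Gaussian noise per channel. All
#' randomness flows from the single `random_seed`.
#'
#' @param start_date First day of the season.
#' @param n_days Season length, days, >= 1.
#' @param t_mean_annual Annual mean of the daily mean temperature, degC.
#' @param t_amplitude Seasonal half-range of the daily mean, degC.
#' @param diurnal_range Tmax - Tmin, degC.
#' @param rh_base Mean of daily RH mean, percent.
#' @param wind_mean Mean wind speed at 10 m, m/s.
#' @param noise_sd Named list of per-channel noise standard deviations:
#'   `temp` (degC), `rh` (percent), `wind` (m/s).
#' @param random_seed Integer seed.
#' @return A list of class `season_spec`.
#' @export
season_spec <- function(start_date, n_days,
                        t_mean_annual = 25, t_amplitude = 8,
                        diurnal_range = 12, rh_base = 55, wind_mean = 3,
                        noise_sd = list(temp = 1.5, rh = 8, wind = 0.8),
                        random_seed = 1L) {
  start_date <- as_date_strict(start_date, "start_date")
  if (n_days < 1) abort_input("`n_days` must be >= 1.")
  structure(
    list(start_date = start_date, n_days = as.integer(n_days),
         t_mean_annual = t_mean_annual, t_amplitude = t_amplitude,
         diurnal_range = diurnal_range, rh_base = rh_base,
         wind_mean = wind_mean, noise_sd = noise_sd,
         random_seed = as.integer(random_seed)),
    class = "season_spec"
  )
}

#' Hot semi-arid preset (Gadap, Karachi)
#'
#' Season spec emulating the 9-month lemon season at the trial site: a hot
#' semi-arid regime whose deterministic summer peak already puts daily
#' maxima at 48 degC, with noise carrying individual days into the low 50s
#' — matching a site where shaded-sensor readings peaked at 52 degC.
#'
#' @param start_date Default 1 February 2018.
#' @param n_days Default 270 (9 months).
#' @param random_seed Integer seed.
#' @return A [season_spec()].
#' @export
karachi_season_spec <- function(start_date = as.Date("2018-02-01"),
                                n_days = 270, random_seed = 1L) {
  season_spec(start_date, n_days,
              t_mean_annual = 29, t_amplitude = 11, diurnal_range = 16,
              rh_base = 55, wind_mean = 3.5,
              noise_sd = list(temp = 1.5, rh = 8, wind = 0.8),
              random_seed = random_seed)
}

#' Generate a synthetic daily weather season
#'
#' Deterministic for a given seed. Daily mean temperature follows
#' `t_mean_annual + t_amplitude * cos(2 pi (doy - 166) / 365)` plus noise;
#' Tmax/Tmin sit half a diurnal range above/below it. RH runs against the
#' temperature cycle (drier at the hot peak) with RHmax/RHmin split around
#' the daily mean and clamped to \[5, 100\]. Wind is folded Gaussian around
#' `wind_mean`, reported at 10 m. The output satisfies every daily-weather
#' invariant by construction.
#'
#' @param spec A [season_spec()].
#' @return Tibble with columns `date`, `t_max`, `t_min`, `rh_max`,
#'   `rh_min`, `wind_speed`.
#' @export
generate_weather_season <- function(spec) {
  stopifnot(inherits(spec, "season_spec"))
  n <- spec$n_days
  dates <- spec$start_date + seq_len(n) - 1
  doy <- as.integer(format(dates, "%j"))
  seasonal <- cos(2 * pi * (doy - 166) / 365)

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$random_seed)

  t_mean <- spec$t_mean_annual + spec$t_amplitude * seasonal +
    rnorm(n, 0, spec$noise_sd$temp)
  half_range <- spec$diurnal_range / 2
  t_max <- t_mean + half_range
  t_min <- t_mean - half_range

  # RH runs against the seasonal temperature anomaly (drier at the hot peak)
  rh_mean <- spec$rh_base - 1.5 * spec$t_amplitude * seasonal +
    rnorm(n, 0, spec$noise_sd$rh)
  rh_max <- pmin(pmax(rh_mean + 18, 5), 100)
  rh_min <- pmin(pmax(rh_mean - 18, 5), 100)
  rh_min <- pmin(rh_min, rh_max)

  wind <- abs(rnorm(n, spec$wind_mean, spec$noise_sd$wind))

  tibble(date = dates, t_max = t_max, t_min = t_min,
         rh_max = rh_max, rh_min = rh_min, wind_speed = wind)
}

#' Simulate an hourly soil-moisture / air sensor trace
#'
#' Emulates the field node: one record per hour of volumetric soil moisture
#' theta, air temperature and RH. Within each day theta declines with the
#' day's ETc over hours 0-17 and sits at the bookkeeping end-of-day level
#' from 18:00 (an evening water turn: on refill days the evening hours read
#' field capacity). The morning segment is centred so that, noise-free and
#' away from the physical bounds, the daily mean theta inverted through
#' [depletion_from_moisture()] equals the day's initial (start-of-day)
#' depletion exactly — the anchoring convention [run_water_balance()] uses.
#' Clipping to the physical range \[0.8 theta_wp, theta_fc\] can perturb the
#' mean slightly for days that touch the bounds.
#'
#' Air temperature follows a cosine between the day's extremes (maximum at
#' 15:00); RH mirrors it between the day's RH extremes.
#'
#' @param weather Daily weather tibble (as from
#'   [generate_weather_season()]).
#' @param soil A [soil_profile()].
#' @param crop A [crop_profile()] (root depth converts depletion to theta).
#' @param daily_etc Numeric vector of daily ETc, mm, same length as
#'   `weather` rows.
#' @param irrigation_log Tibble with columns `date`, `depth_mm` of
#'   irrigation events; dates must fall within the weather range.
#' @param initial_depletion Starting depletion, mm.
#' @param noise_sd Gaussian noise on hourly theta, m3/m3. Default 0.
#' @param seed Integer seed for the noise.
#' @return Tibble with columns `timestamp`, `date`, `hour`, `theta`,
#'   `t_air`, `rh`.
#' @export
simulate_sensor <- function(weather, soil, crop, daily_etc,
                            irrigation_log = NULL, initial_depletion = 0,
                            noise_sd = 0, seed = 1L) {
  stopifnot(inherits(soil, "soil_profile"), inherits(crop, "crop_profile"))
  weather <- validate_daily_weather(weather)
  n <- nrow(weather)
  if (length(daily_etc) != n) {
    abort_input("`daily_etc` must have one value per weather day.")
  }
  irr <- rep(0, n)
  if (!is.null(irrigation_log) && nrow(irrigation_log)) {
    idx <- match(as_date_strict(irrigation_log$date), weather$date)
    if (anyNA(idx)) abort_input("irrigation dates outside the weather range.")
    irr[idx] <- irr[idx] + irrigation_log$depth_mm
  }
  zr <- crop$effective_root_depth
  taw <- total_available_water(soil, zr)
  theta_of_dr <- function(dr) soil$theta_fc - dr / (1000 * zr)

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  hours <- 0:23
  rows <- vector("list", n)
  dr <- min(max(initial_depletion, 0), taw)
  for (i in seq_len(n)) {
    # Two-segment within-day profile whose 24-h mean is exactly the day's
    # initial depletion dr: hours 18-23 sit at the bookkeeping end-of-day
    # level (post-irrigation), hours 0-17 decline linearly with the day's
    # ET around the centring level that restores the mean.
    level_pm <- min(max(dr + daily_etc[i] - irr[i], 0), taw)
    centre_am <- (24 * dr - 6 * level_pm) / 18
    dr_hourly <- c(centre_am + daily_etc[i] * ((0:17 + 0.5) / 18 - 0.5),
                   rep(level_pm, 6))
    theta <- theta_of_dr(dr_hourly)
    if (noise_sd > 0) theta <- theta + rnorm(24, 0, noise_sd)
    theta <- pmin(pmax(theta, soil$theta_wp * 0.8), soil$theta_fc)

    tcycle <- (cos(2 * pi * (hours - 15) / 24) + 1) / 2  # 1 at 15h, min at 03h
    t_air <- weather$t_min[i] + (weather$t_max[i] - weather$t_min[i]) * tcycle
    rh <- weather$rh_max[i] - (weather$rh_max[i] - weather$rh_min[i]) * tcycle

    rows[[i]] <- tibble(
      timestamp = as.POSIXct(weather$date[i], tz = "UTC") + hours * 3600,
      date = weather$date[i], hour = hours,
      theta = theta, t_air = t_air, rh = rh
    )
    dr <- min(max(dr + daily_etc[i] - irr[i], 0), taw)
  }
  dplyr::bind_rows(rows)
}

#' Aggregate an hourly sensor trace to daily records
#'
#' Daily Tmax/Tmin and RHmax/RHmin are the day's hourly extrema; theta is
#' the arithmetic mean of the 24 hourly readings. Days with fewer than 24
#' records are dropped with a warning.
#'
#' @param trace Tibble as from [simulate_sensor()]; columns `date`,
#'   `theta`, `t_air`, `rh`.
#' @return Tibble with columns `date`, `t_max`, `t_min`, `rh_max`,
#'   `rh_min`, `theta_mean`.
#' @export
hourly_to_daily <- function(trace) {
  needed <- c("date", "theta", "t_air", "rh")
  if (!all(needed %in% names(trace))) {
    abort_input("`trace` needs columns date, theta, t_air, rh.")
  }
  out <- trace |>
    dplyr::group_by(date = as.Date(.data$date)) |>
    dplyr::summarise(
      n_hours = dplyr::n(),
      t_max = max(.data$t_air), t_min = min(.data$t_air),
      rh_max = max(.data$rh), rh_min = min(.data$rh),
      theta_mean = mean(.data$theta), .groups = "drop"
    )
  partial <- out$n_hours < 24
  if (any(partial)) {
    warn(sprintf("dropping %d partial day(s) with < 24 hourly records.",
                 sum(partial)))
    out <- out[!partial, ]
  }
  dplyr::select(out, -"n_hours")
}

#' Irrigation logs of the two trial plots
#'
#' The 17 recorded irrigation events of the season-long field comparison:
#' day of year (day 1 = 1 January), litres applied to the
#' traditionally-irrigated plot (Area A) and to the sensor-scheduled plot
#' (Area B; 0 where the decision system recommended no irrigation on the
#' farmer's turn).
#'
#' @return Tibble with columns `day_of_year`, `area_a_l`, `area_b_l`.
#' @export
table2_fixture <- function() {
  tibble(
    day_of_year = c(32, 67, 78, 89, 105, 115, 131, 159, 169, 179, 192,
                    210, 220, 226, 260, 291, 304),
    area_a_l = c(7110, 5273, 6588, 5212, 4873, 5553, 5452, 7117, 5277,
                 4224, 5833, 6563, 4624, 7856, 5104, 4316, 5894),
    area_b_l = c(6266, 0, 4799, 0, 6399, 0, 5120, 0, 3922, 0, 3924,
                 7546, 0, 0, 0, 7242, 0)
  )
}
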