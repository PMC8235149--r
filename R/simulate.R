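#' Simulate an irrigation season under a scheduling policy
#'
#' Runs the whole chain on a daily weather table: reference ET, crop
#' coefficient, crop ET, root-zone depletion, and an irrigation policy
#' constrained to the water-turn calendar. Two policies are provided:
#'
#' * `"dss"` — demand-driven: on each turn day, project end-of-day
#'   depletion forward to the days before the next turn (forecast ETc is
#'   the mean of the last `k` realized values, or the realized future
#'   values when `foresight = TRUE`); if the projection reaches RAW before
#'   the next turn can act, irrigate now with the net refill depth.
#' * `"every_turn"` — the traditional fixed calendar: flood a fixed gross
#'   depth (`fixed_depth_mm`) on every turn day regardless of need, the way
#'   the comparison plot was farmed; water beyond the current deficit
#'   drains below the root zone as deep percolation.
#'
#' Irrigation is only ever applied on turn days. Within a day the order is
#' ETc first, then irrigation (end-of-day convention).
#'
#' @param weather Daily weather tibble (see [validate_daily_weather()]).
#' @param site A [site_geometry()].
#' @param crop A [crop_profile()].
#' @param soil A [soil_profile()].
#' @param calendar A [warabandi_calendar()].
#' @param flow A [flow_spec()].
#' @param policy `"dss"`, `"every_turn"` or `"none"` (no irrigation; pure
#'   drawdown).
#' @param initial_depletion Starting D_r, mm. Default 0.
#' @param foresight With `policy = "dss"`, use the realized future ETc
#'   instead of the persistence forecast (useful for policy analysis).
#' @param k Trailing days in the persistence forecast. Default 3.
#' @param fixed_depth_mm Gross application of the every-turn policy, mm per
#'   event. Default 60, a typical flood-basin application.
#' @param ... Passed to [calc_et0()] (e.g. `k_rs`, `ea_pairing`).
#' @return An object of class `season_sim`: a list with `daily` (the full
#'   per-day log: weather, ET terms, `kc`, `etc`, `etc_actual`,
#'   `dr_initial`, `dr_final`, `taw`, `raw`, `percolation`, `irrigation`,
#'   `action`), `events` (one
#'   row per irrigation: `date`, `depth_mm`, `volume_l`, `duration_min`,
#'   `acre_inches`) and `params`.
#' @examples
#' \donttest{
#' spec <- karachi_season_spec(random_seed = 7)
#' sim <- simulate_season(generate_weather_season(spec),
#'                        site_geometry(24.9, 67.3, 20),
#'                        lemon_profile(spec$start_date),
#'                        soil_profile(0.32, 0.12),
#'                        warabandi_calendar(spec$start_date + 1),
#'                        flow_spec(200))
#' glance(sim)
#' }
#' @export
simulate_season <- function(weather, site, crop, soil, calendar, flow,
                            policy = c("dss", "every_turn", "none"),
                            initial_depletion = 0, foresight = FALSE,
                            k = 3, fixed_depth_mm = 60, ...) {
  policy <- match.arg(policy)
  stopifnot(inherits(crop, "crop_profile"), inherits(soil, "soil_profile"),
            inherits(calendar, "warabandi_calendar"),
            inherits(flow, "flow_spec"))
  daily <- calc_et0(weather, site, ...) |> calc_etc(crop)
  n <- nrow(daily)
  taw <- total_available_water(soil, crop$effective_root_depth)
  p <- crop$depletion_fraction_p
  raw <- readily_available_water(taw, p)
  turn <- is_turn_day(calendar, daily$date)

  dr <- min(max(initial_depletion, 0), taw)
  dr_initial <- dr_final <- irrigation <- perc <- etc_act <- numeric(n)
  action <- character(n)
  for (i in seq_len(n)) {
    dr_initial[i] <- dr
    dr_et <- dr + daily$etc[i]            # end-of-day depletion before irrigation
    irr <- 0
    act <- "none"
    if (turn[i] && policy != "none") {
      irrigate <- if (policy == "every_turn") {
        TRUE
      } else {
        # project end-of-day depletion for today and the days strictly
        # before the next turn; irrigate now if any reaches RAW
        nt <- next_turn(daily$date[i], calendar)
        gap <- if (is.na(nt)) 1 else as.numeric(nt - daily$date[i])
        ahead <- seq_len(max(gap - 1, 0))
        proj_rates <- if (foresight) {
          daily$etc[pmin(i + ahead, n)]
        } else {
          rep(mean(tail(daily$etc[max(1, i - k + 1):i], k)), length(ahead))
        }
        proj <- dr_et + cumsum(c(0, proj_rates))
        any(pmin(proj, taw) >= raw)
      }
      if (irrigate) {
        irr <- if (policy == "every_turn") {
          fixed_depth_mm                  # gross flood application
        } else {
          min(dr_et, taw)                 # net refill to field capacity
        }
        if (irr > 0) act <- "irrigate"
      }
    }
    dr_new <- dr_et - irr
    etc_act[i] <- daily$etc[i] - max(0, dr_new - taw)
    perc[i] <- max(0, -dr_new)
    dr <- min(max(dr_new, 0), taw)
    dr_final[i] <- dr
    irrigation[i] <- irr
    action[i] <- act
  }

  daily$turn_day <- turn
  daily$etc_actual <- etc_act
  daily$dr_initial <- dr_initial
  daily$dr_final <- dr_final
  daily$taw <- taw
  daily$raw <- raw
  daily$irrigation <- irrigation
  daily$percolation <- perc
  daily$action <- action

  ev <- daily[daily$irrigation > 0,
              c("date", "irrigation")]
  events <- tibble(
    date = ev$date,
    depth_mm = ev$irrigation,
    volume_l = ev$irrigation * flow$field_area,
    duration_min = ev$irrigation * flow$field_area / flow$flow_rate,
    acre_inches = ev$irrigation * flow$field_area / L_PER_ACRE_INCH
  )

  structure(
    list(daily = daily, events = events,
         params = list(policy = policy, taw = taw, raw = raw,
                       foresight = foresight, k = k,
                       site = site, crop = crop, soil = soil,
                       calendar = calendar, flow = flow)),
    class = "season_sim"
  )
}

#' @export
print.season_sim <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    paste0("<season_sim> %s policy: %d days, %d irrigation event(s), ",
           "%.0f L total (%.1f mm), max D_r %.1f / RAW %.1f mm\n"),
    x$params$policy, g$n_days, g$n_events, g$total_volume_l,
    g$total_depth_mm, g$max_dr_final, x$params$raw))
  invisible(x)
}

#' Tidy a simulated season
#'
#' @param x A `season_sim`.
#' @param ... Unused.
#' @return The per-day log tibble.
#' @export
tidy.season_sim <- function(x, ...) x$daily

#' One-row summary of a simulated season
#'
#' @param x A `season_sim`.
#' @param ... Unused.
#' @return One-row tibble: days, events, water totals, ET totals, depletion
#'   extremes, stress-day count (days ending above RAW).
#' @export
glance.season_sim <- function(x, ...) {
  d <- x$daily
  tibble(
    policy = x$params$policy,
    n_days = nrow(d),
    n_events = nrow(x$events),
    total_depth_mm = sum(d$irrigation),
    total_volume_l = sum(x$events$volume_l),
    total_et0_mm = sum(d$et0),
    total_etc_mm = sum(d$etc),
    total_percolation_mm = sum(d$percolation),
    max_dr_final = max(d$dr_final),
    stress_days = sum(d$dr_final > x$params$raw)
  )
}
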