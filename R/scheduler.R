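#' Rotational water-turn calendar
#'
#' Under Warabandi each farmer receives canal water on scheduled turn days
#' only. The calendar is either periodic (an anchor turn date plus a period,
#' 7 days for the usual weekly turn) or an explicit strictly increasing list
#' of turn dates overriding the periodic rule.
#'
#' @param turn_anchor Date of any known turn.
#' @param period_days Days between turns, integer >= 1. Default 7.
#' @param turn_dates Optional explicit Date vector of turns (strictly
#'   increasing); when supplied, `turn_anchor`/`period_days` are ignored.
#' @return A list of class `warabandi_calendar`.
#' @examples
#' warabandi_calendar(as.Date("2018-02-02"))   # weekly Friday turns
#' @export
warabandi_calendar <- function(turn_anchor = NULL, period_days = 7,
                               turn_dates = NULL) {
  if (!is.null(turn_dates)) {
    turn_dates <- as_date_strict(turn_dates, "turn_dates")
    if (is.unsorted(turn_dates, strictly = TRUE)) {
      abort_input("`turn_dates` must be strictly increasing.")
    }
  } else {
    if (is.null(turn_anchor)) {
      abort_input("supply `turn_anchor` or an explicit `turn_dates` list.")
    }
    turn_anchor <- as_date_strict(turn_anchor, "turn_anchor")
    period_days <- as.integer(period_days)
    if (is.na(period_days) || period_days < 1) {
      abort_input("`period_days` must be an integer >= 1.")
    }
  }
  structure(list(turn_anchor = turn_anchor, period_days = period_days,
                 turn_dates = turn_dates),
            class = "warabandi_calendar")
}

#' Is a date a turn day?
#'
#' @param calendar A [warabandi_calendar()].
#' @param date Date vector.
#' @return Logical vector.
#' @export
is_turn_day <- function(calendar, date) {
  stopifnot(inherits(calendar, "warabandi_calendar"))
  date <- as_date_strict(date)
  if (!is.null(calendar$turn_dates)) {
    date %in% calendar$turn_dates
  } else {
    as.numeric(date - calendar$turn_anchor) %% calendar$period_days == 0
  }
}

#' Latest turn on or before a needed date
#'
#' The Warabandi constraint: water is only available on turn days, so an
#' irrigation needed on, say, a Monday must be brought forward to the
#' latest turn on or before it (the previous Friday under weekly Friday
#' turns).
#'
#' @param need_date Date the depletion is forecast to reach RAW.
#' @param calendar A [warabandi_calendar()].
#' @return The aligned turn date (<= `need_date`).
#' @export
align_to_turn <- function(need_date, calendar) {
  stopifnot(inherits(calendar, "warabandi_calendar"))
  need_date <- as_date_strict(need_date, "need_date")
  if (!is.null(calendar$turn_dates)) {
    prior <- calendar$turn_dates[calendar$turn_dates <= need_date]
    if (!length(prior)) {
      abort("no turn on or before the need date.",
            class = "warabandi_no_feasible_turn")
    }
    max(prior)
  } else {
    k <- floor(as.numeric(need_date - calendar$turn_anchor) /
                 calendar$period_days)
    calendar$turn_anchor + k * calendar$period_days
  }
}

#' Next turn strictly after a date
#'
#' @param date Reference date.
#' @param calendar A [warabandi_calendar()].
#' @return The next turn date, or `NA` if an explicit list is exhausted.
#' @export
next_turn <- function(date, calendar) {
  stopifnot(inherits(calendar, "warabandi_calendar"))
  date <- as_date_strict(date)
  if (!is.null(calendar$turn_dates)) {
    later <- calendar$turn_dates[calendar$turn_dates > date]
    if (!length(later)) return(as.Date(NA)) else return(min(later))
  }
  k <- floor(as.numeric(date - calendar$turn_anchor) / calendar$period_days)
  calendar$turn_anchor + (k + 1) * calendar$period_days
}

#' Field area and supply flow for output conversions
#'
#' @param flow_rate Supply flow while the turn is open, litres/minute, > 0.
#' @param field_area Irrigated area, square metres, > 0. Default 2 acres,
#'   the size of each trial plot.
#' @return A list of class `flow_spec`.
#' @export
flow_spec <- function(flow_rate, field_area = 2 * M2_PER_ACRE) {
  check_finite_numeric(flow_rate, "flow_rate")
  check_finite_numeric(field_area, "field_area")
  if (flow_rate <= 0 || field_area <= 0) {
    abort_input("`flow_rate` and `field_area` must be > 0.")
  }
  structure(list(flow_rate = flow_rate, field_area = field_area),
            class = "flow_spec")
}

#' Forecast the date depletion reaches RAW
#'
#' Persistence forecast: project depletion forward at the mean of the last
#' `k` days' ETc. The need date is the earliest day within the horizon whose
#' projected end-of-day depletion reaches RAW; `NA` if never reached (e.g.
#' zero recent ETc).
#'
#' @param state A [water_balance_state()] (end of "today").
#' @param recent_etc Numeric vector of recent daily ETc values, most recent
#'   last; must be non-empty.
#' @param horizon_days Days to look ahead, >= 1. Default 30.
#' @param k Number of trailing ETc values averaged. Default 3.
#' @return Date, or `NA` if RAW is not reached within the horizon.
#' @export
forecast_need_date <- function(state, recent_etc, horizon_days = 30, k = 3) {
  stopifnot(inherits(state, "water_balance_state"))
  if (!length(recent_etc)) abort_input("`recent_etc` must be non-empty.")
  check_finite_numeric(recent_etc, "recent_etc")
  if (horizon_days < 1) abort_input("`horizon_days` must be >= 1.")
  if (state$depletion_dr >= state$raw) return(state$date)
  rate <- mean(tail(recent_etc, k))
  if (rate <= 0) return(as.Date(NA))
  # epsilon guards the ceiling against float noise in RAW - D_r
  days <- ceiling((state$raw - state$depletion_dr) / rate - 1e-9)
  if (days > horizon_days) return(as.Date(NA))
  state$date + days
}

#' Turn-aligned irrigation recommendation
#'
#' Composes the forecast and the turn calendar into the farmer-facing
#' recommendation: forecast when depletion will reach RAW, pull the event
#' back to the latest turn on or before that date, and size the application
#' as the depletion projected at the end of the turn date (refill to field
#' capacity), expressed simultaneously as depth (mm), volume (L), run time
#' (minutes at the supply flow) and acre-inches. If the aligned turn
#' precedes the state's own date, the next turn is recommended instead with
#' a stress warning (`missed_turn = TRUE`). If no irrigation is projected to
#' be needed within the horizon, `NULL` is returned.
#'
#' @param state A [water_balance_state()].
#' @param recent_etc Recent daily ETc values, most recent last.
#' @param calendar A [warabandi_calendar()].
#' @param flow A [flow_spec()].
#' @param horizon_days,k Passed to [forecast_need_date()].
#' @param depth_at Either `"turn"` (default: depth is the depletion
#'   projected at the end of the turn date) or `"current"` (today's
#'   depletion).
#' @return A one-row tibble (class `irrigation_recommendation`) with
#'   columns `need_date`, `turn_date`, `missed_turn`, `depth_mm`,
#'   `volume_l`, `duration_min`, `acre_inches`; or `NULL`.
#' @export
recommend <- function(state, recent_etc, calendar, flow,
                      horizon_days = 30, k = 3,
                      depth_at = c("turn", "current")) {
  depth_at <- match.arg(depth_at)
  stopifnot(inherits(flow, "flow_spec"))
  need <- forecast_need_date(state, recent_etc, horizon_days, k)
  if (is.na(need)) return(NULL)
  turn <- align_to_turn(need, calendar)
  missed <- FALSE
  if (turn < state$date) {
    warn("aligned turn already past; recommending next turn (crop stress likely).")
    turn <- next_turn(state$date, calendar)
    missed <- TRUE
    if (is.na(turn)) {
      abort("no future turn available.", class = "warabandi_no_feasible_turn")
    }
  }
  rate <- mean(tail(recent_etc, k))
  depth <- if (depth_at == "turn") {
    min(state$depletion_dr + rate * as.numeric(turn - state$date), state$taw)
  } else {
    state$depletion_dr
  }
  if (depth <= 0) return(NULL)
  volume <- depth * flow$field_area      # 1 mm over 1 m2 = 1 L
  out <- tibble(
    need_date = need, turn_date = turn, missed_turn = missed,
    depth_mm = depth, volume_l = volume,
    duration_min = volume / flow$flow_rate,
    acre_inches = volume / L_PER_ACRE_INCH
  )
  class(out) <- c("irrigation_recommendation", class(out))
  out
}

#' Convert an irrigation volume to the farmer's preferred output unit
#'
#' Farmers variously reason in volume, run time at a known supply flow, or
#' acre-inches; the delivered water is identical whichever unit is shown.
#'
#' @param volume_l Volume, litres, >= 0.
#' @param flow A [flow_spec()] (needed for the time unit).
#' @param unit One of `"volume"` (litres), `"time"` (minutes),
#'   `"acre_inch"`.
#' @return The quantity in the requested unit.
#' @export
convert_output <- function(volume_l, flow, unit = c("volume", "time", "acre_inch")) {
  check_finite_numeric(volume_l, "volume_l")
  if (any(volume_l < 0)) abort_input("`volume_l` must be >= 0.")
  stopifnot(inherits(flow, "flow_spec"))
  unit <- tryCatch(match.arg(unit), error = function(e) {
    abort_input(paste0("unknown output unit: ", unit[1]))
  })
  switch(unit,
         volume = volume_l,
         time = volume_l / flow$flow_rate,
         acre_inch = volume_l / L_PER_ACRE_INCH)
}

#' Invert an output quantity back to litres
#'
#' @param quantity Value in `unit`.
#' @param flow A [flow_spec()].
#' @param unit As in [convert_output()].
#' @return Volume in litres.
#' @export
output_to_volume <- function(quantity, flow, unit = c("volume", "time", "acre_inch")) {
  unit <- match.arg(unit)
  stopifnot(inherits(flow, "flow_spec"))
  switch(unit,
         volume = quantity,
         time = quantity * flow$flow_rate,
         acre_inch = quantity * L_PER_ACRE_INCH)
}
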