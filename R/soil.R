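#' Describe soil water-holding properties
#'
#' @param theta_fc Volumetric water content at field capacity, m3/m3.
#' @param theta_wp Volumetric water content at permanent wilting point,
#'   m3/m3. Must satisfy 0 < theta_wp < theta_fc < 1.
#' @return A list of class `soil_profile`.
#' @examples
#' soil_profile(0.32, 0.12) # sandy clay loam
#' @export
soil_profile <- function(theta_fc, theta_wp) {
  check_finite_numeric(theta_fc, "theta_fc")
  check_finite_numeric(theta_wp, "theta_wp")
  if (!(theta_wp > 0 && theta_fc > theta_wp && theta_fc < 1)) {
    abort_input("need 0 < theta_wp < theta_fc < 1.")
  }
  structure(list(theta_fc = theta_fc, theta_wp = theta_wp),
            class = "soil_profile")
}

#' Total available water in the root zone
#'
#' TAW = 1000 (theta_fc - theta_wp) Z_r, the plant-extractable storage of
#' the root zone in mm of water depth.
#'
#' @param soil A [soil_profile()].
#' @param root_depth Effective rooting depth Z_r, metres, > 0.
#' @return TAW, mm.
#' @export
total_available_water <- function(soil, root_depth) {
  stopifnot(inherits(soil, "soil_profile"))
  check_finite_numeric(root_depth, "root_depth")
  if (any(root_depth <= 0)) abort_input("`root_depth` must be > 0.")
  taw <- 1000 * (soil$theta_fc - soil$theta_wp) * root_depth
  if (any(taw <= 0)) {
    abort(
      "soil has zero water-holding capacity (theta_fc == theta_wp).",
      class = "warabandi_zero_capacity"
    )
  }
  taw
}

#' Readily available water
#'
#' RAW = p_eff * TAW, the depletion a crop tolerates without stress. With
#' `adjust = TRUE` the depletion fraction is corrected for evaporative
#' demand, p_eff = p + 0.04 (5 - ETc), clamped to \[0.1, 0.8\]: crops
#' tolerate deeper depletion when demand is low and shallower when it is
#' high. Off by default.
#'
#' @param taw Total available water, mm, > 0.
#' @param p Tabulated depletion fraction, in (0, 1).
#' @param etc_today Today's crop evapotranspiration, mm/day (only used when
#'   `adjust = TRUE`).
#' @param adjust Apply the demand correction?
#' @return RAW, mm, in (0, taw\].
#' @export
readily_available_water <- function(taw, p, etc_today = NA_real_,
                                    adjust = FALSE) {
  check_finite_numeric(taw, "taw")
  if (any(taw <= 0)) abort_input("`taw` must be > 0.")
  if (any(p <= 0 | p >= 1)) abort_input("`p` must lie in (0, 1).")
  p_eff <- if (adjust) {
    check_finite_numeric(etc_today, "etc_today")
    pmin(pmax(p + 0.04 * (5 - etc_today), 0.1), 0.8)
  } else {
    p
  }
  pmin(p_eff * taw, taw)
}

#' Root-zone depletion from a soil-moisture reading
#'
#' D_r = 1000 (theta_fc - theta_mean) Z_r, clipped to \[0, TAW\]: how far the
#' root zone has drawn down from field capacity given the (daily mean)
#' volumetric moisture a sensor reports.
#'
#' @param soil A [soil_profile()].
#' @param theta_mean Mean volumetric water content, m3/m3, in \[0, 1\].
#' @param root_depth Z_r, metres.
#' @return Depletion, mm, in \[0, TAW\].
#' @export
depletion_from_moisture <- function(soil, theta_mean, root_depth) {
  stopifnot(inherits(soil, "soil_profile"))
  check_finite_numeric(theta_mean, "theta_mean")
  if (any(theta_mean < 0 | theta_mean > 1)) {
    abort_input("`theta_mean` must lie in [0, 1].")
  }
  taw <- total_available_water(soil, root_depth)
  dr <- 1000 * (soil$theta_fc - theta_mean) * root_depth
  pmin(pmax(dr, 0), taw)
}

#' A day's water-balance state
#'
#' Snapshot of the root zone on a date: depletion D_r plus its TAW/RAW
#' context, as a one-row tibble so states stack into a season log.
#'
#' @param date Calendar date.
#' @param depletion_dr Root-zone depletion, mm, in \[0, taw\].
#' @param taw Total available water, mm.
#' @param raw Readily available water, mm, in (0, taw\].
#' @return One-row tibble of class `water_balance_state`.
#' @export
water_balance_state <- function(date, depletion_dr, taw, raw) {
  date <- as_date_strict(date)
  check_finite_numeric(depletion_dr, "depletion_dr")
  check_finite_numeric(taw, "taw")
  check_finite_numeric(raw, "raw")
  if (depletion_dr < 0 || depletion_dr > taw) {
    abort_input("`depletion_dr` must lie in [0, taw].")
  }
  if (raw <= 0 || raw > taw) abort_input("`raw` must lie in (0, taw].")
  out <- tibble(date = date, depletion_dr = depletion_dr,
                taw = taw, raw = raw)
  class(out) <- c("water_balance_state", class(out))
  out
}

#' Advance the water balance one day
#'
#' End-of-day bookkeeping: the day's ETc deepens the depletion, then
#' irrigation and precipitation refill it. The result is clipped to
#' \[0, TAW\]; water pushing depletion below zero leaves the root zone as
#' deep percolation (returned in the `percolation` attribute-free column of
#' season runs; here the clipped state is returned).
#'
#' @param state A [water_balance_state()].
#' @param etc Crop evapotranspiration of the day, mm, >= 0.
#' @param irrigation_depth Irrigation applied that day, mm, >= 0.
#' @param precipitation Rainfall that day, mm, >= 0 (default 0: the target
#'   region is arid).
#' @return The next day's [water_balance_state()].
#' @export
advance_day <- function(state, etc, irrigation_depth = 0, precipitation = 0) {
  stopifnot(inherits(state, "water_balance_state"))
  check_finite_numeric(etc, "etc")
  check_finite_numeric(irrigation_depth, "irrigation_depth")
  check_finite_numeric(precipitation, "precipitation")
  if (etc < 0 || irrigation_depth < 0 || precipitation < 0) {
    abort_input("fluxes must be >= 0.")
  }
  dr <- state$depletion_dr + etc - irrigation_depth - precipitation
  dr <- min(max(dr, 0), state$taw)
  water_balance_state(state$date + 1, dr, state$taw, state$raw)
}

#' Is irrigation needed?
#'
#' The daily trigger: irrigation is needed exactly when end-of-day depletion
#' has reached the readily-available-water threshold, D_r >= RAW (boundary
#' inclusive).
#'
#' @param state A [water_balance_state()].
#' @return Logical.
#' @export
irrigation_needed <- function(state) {
  stopifnot(inherits(state, "water_balance_state"))
  state$depletion_dr >= state$raw
}

#' Net refill depth
#'
#' The irrigation depth that returns the root zone to field capacity:
#' exactly the current depletion.
#'
#' @param state A [water_balance_state()].
#' @return Depth, mm.
#' @export
refill_depth <- function(state) {
  stopifnot(inherits(state, "water_balance_state"))
  state$depletion_dr
}

#' Run the daily root-zone water balance over a season
#'
#' Takes a daily table carrying `date` and `etc` (and optionally
#' `irrigation`, `precipitation` and a sensor-derived `theta_mean`) and
#' book-keeps depletion day by day. Ordering within a day: the day's ETc is
#' applied first (final depletion), then irrigation and precipitation.
#' When a `theta_mean` column is present, each day's starting ("initial")
#' depletion is re-anchored from the sensor via [depletion_from_moisture()]
#' before the day's fluxes are applied; otherwise bookkeeping carries over.
#'
#' @param daily Tibble with columns `date`, `etc`, optional `irrigation`
#'   (mm), `precipitation` (mm), `theta_mean` (m3/m3).
#' @param crop A [crop_profile()] (root depth and depletion fraction).
#' @param soil A [soil_profile()].
#' @param initial_depletion Starting D_r, mm; default 0 (field at capacity).
#' @param raw_adjust Demand-adjust RAW daily from ETc? Default `FALSE`.
#' @return `daily` with columns `dr_initial`, `dr_final` (end-of-day, after
#'   all fluxes), `etc_actual` (water actually extracted: the day's ETc
#'   truncated when the root zone runs dry at TAW, so the mass balance
#'   closes exactly), `taw`, `raw`, `percolation` (mm lost below the root
#'   zone) and `trigger` (logical, D_r >= RAW at end of day) appended.
#'   Conservation holds identically:
#'   `sum(etc_actual) - sum(irrigation) - sum(precipitation)` equals
#'   `dr_final[n] - dr_initial[1] - sum(percolation)`.
#' @export
run_water_balance <- function(daily, crop, soil, initial_depletion = 0,
                              raw_adjust = FALSE) {
  stopifnot(inherits(crop, "crop_profile"), inherits(soil, "soil_profile"))
  if (!all(c("date", "etc") %in% names(daily))) {
    abort_input("`daily` needs date and etc columns.")
  }
  daily <- as_tibble(daily)
  daily$date <- as_date_strict(daily$date)
  n <- nrow(daily)
  irr <- if ("irrigation" %in% names(daily)) daily$irrigation else rep(0, n)
  prc <- if ("precipitation" %in% names(daily)) daily$precipitation else rep(0, n)
  anchored <- "theta_mean" %in% names(daily)

  taw <- total_available_water(soil, crop$effective_root_depth)
  p <- crop$depletion_fraction_p
  dr_initial <- dr_final <- raw <- perc <- etc_act <- numeric(n)
  dr <- min(max(initial_depletion, 0), taw)
  for (i in seq_len(n)) {
    if (anchored && !is.na(daily$theta_mean[i])) {
      dr <- depletion_from_moisture(soil, daily$theta_mean[i],
                                    crop$effective_root_depth)
    }
    dr_initial[i] <- dr
    raw[i] <- readily_available_water(taw, p, etc_today = daily$etc[i],
                                      adjust = raw_adjust)
    dr_new <- dr + daily$etc[i] - irr[i] - prc[i]
    # extraction stops once the root zone is dry: unmet demand at TAW
    etc_act[i] <- daily$etc[i] - max(0, dr_new - taw)
    perc[i] <- max(0, -dr_new)
    dr <- min(max(dr_new, 0), taw)
    dr_final[i] <- dr
  }
  daily$irrigation <- irr
  daily$precipitation <- prc
  daily$etc_actual <- etc_act
  daily$dr_initial <- dr_initial
  daily$dr_final <- dr_final
  daily$taw <- taw
  daily$raw <- raw
  daily$percolation <- perc
  daily$trigger <- dr_final >= raw
  daily
}
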