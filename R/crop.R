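#' Define a crop's coefficient curve and rooting characteristics
#'
#' A crop profile carries everything the water balance needs about the crop:
#' the staged Kc curve (initial / development / mid / late in the usual
#' four-stage form, though any number of stages is accepted), the effective
#' rooting depth Z_r used for total available water, the depletion fraction
#' p used for readily available water, and the planting date anchoring the
#' stage clock.
#'
#' Kc is held constant within a stage whose `interpolate` flag is `FALSE`
#' (initial and mid stages) and ramps linearly from the previous stage's Kc
#' to the stage's own Kc when `TRUE` (development and late stages), giving
#' the standard piecewise-linear FAO curve. Dates past the last stage hold
#' the final Kc: citrus orchards are evergreen, so the curve does not
#' terminate.
#'
#' @param crop_name Label.
#' @param planting_date Date the stage clock starts.
#' @param stages Data frame with columns `stage`, `length_days`,
#'   `kc` and optional logical `interpolate` (default: `TRUE` for stages
#'   named "development" or "late", else `FALSE`).
#' @param effective_root_depth Z_r, metres, > 0.
#' @param depletion_fraction_p Fraction of TAW extractable without stress,
#'   in (0, 1). Default 0.5, the usual value for citrus.
#' @return A list of class `crop_profile`.
#' @examples
#' lemon_profile(as.Date("2018-02-01"))
#' @export
crop_profile <- function(crop_name, planting_date, stages,
                         effective_root_depth,
                         depletion_fraction_p = 0.5) {
  planting_date <- as_date_strict(planting_date, "planting_date")
  stages <- as_tibble(stages)
  needed <- c("stage", "length_days", "kc")
  if (!all(needed %in% names(stages))) {
    abort_input("`stages` needs columns stage, length_days, kc.")
  }
  if (!"interpolate" %in% names(stages)) {
    stages$interpolate <- stages$stage %in% c("development", "late")
  }
  check_finite_numeric(stages$length_days, "length_days")
  check_finite_numeric(stages$kc, "kc")
  if (any(stages$length_days <= 0)) abort_input("stage lengths must be > 0.")
  if (any(stages$kc <= 0)) abort_input("all stage Kc values must be > 0.")
  check_finite_numeric(effective_root_depth, "effective_root_depth")
  if (effective_root_depth <= 0) abort_input("`effective_root_depth` must be > 0.")
  if (depletion_fraction_p <= 0 || depletion_fraction_p >= 1) {
    abort_input("`depletion_fraction_p` must lie in (0, 1).")
  }
  structure(
    list(crop_name = crop_name, planting_date = planting_date,
         stages = stages, effective_root_depth = effective_root_depth,
         depletion_fraction_p = depletion_fraction_p),
    class = "crop_profile"
  )
}

#' Bundled lemon profile
#'
#' Four-stage Kc curve for a flood-irrigated lemon orchard with all stage
#' coefficients inside the 0.6-0.8 band FAO tabulates for citrus: initial
#' 0.65 (60 d), development ramping to 0.75 (60 d), mid 0.75 (90 d), late
#' easing to 0.70 (60 d) — a 270-day season. Effective root depth 1.1 m,
#' depletion fraction 0.5.
#'
#' @param planting_date Stage-clock anchor; default 1 February 2018, the
#'   start of the Gadap trial season.
#' @return A [crop_profile()].
#' @export
lemon_profile <- function(planting_date = as.Date("2018-02-01")) {
  crop_profile(
    crop_name = "lemon",
    planting_date = planting_date,
    stages = tibble(
      stage = c("initial", "development", "mid", "late"),
      length_days = c(60, 60, 90, 60),
      kc = c(0.65, 0.75, 0.75, 0.70),
      interpolate = c(FALSE, TRUE, FALSE, TRUE)
    ),
    effective_root_depth = 1.1,
    depletion_fraction_p = 0.5
  )
}

#' Crop coefficient on given dates
#'
#' Evaluates the staged Kc curve at one or more dates. Within a
#' non-interpolating stage the value is the stage Kc; within an
#' interpolating stage it ramps linearly from the previous stage's Kc at the
#' boundary to the stage Kc at the stage's end, so the curve is continuous.
#' Dates beyond the last stage return the final Kc.
#'
#' @param crop A [crop_profile()].
#' @param date Date vector, each >= the planting date.
#' @return Numeric Kc vector.
#' @export
kc_on_day <- function(crop, date) {
  stopifnot(inherits(crop, "crop_profile"))
  date <- as_date_strict(date)
  das <- as.numeric(date - crop$planting_date) # days after planting, 0-based
  if (any(das < 0)) abort_input("`date` precedes the planting date.")
  st <- crop$stages
  ends <- cumsum(st$length_days)
  starts <- c(0, head(ends, -1))
  vapply(das, function(d) {
    i <- which(d < ends)[1]
    if (is.na(i)) return(st$kc[nrow(st)])
    if (!st$interpolate[i] || i == 1) return(st$kc[i])
    frac <- (d - starts[i] + 1) / st$length_days[i] # reach stage Kc at stage end
    st$kc[i - 1] + frac * (st$kc[i] - st$kc[i - 1])
  }, numeric(1))
}

#' Crop evapotranspiration
#'
#' ETc = Kc * ET0: the reference demand scaled by the crop coefficient.
#'
#' @param et0 Reference evapotranspiration, mm/day, >= 0.
#' @param kc Crop coefficient, > 0.
#' @return ETc, mm/day.
#' @export
crop_evapotranspiration <- function(et0, kc) {
  check_finite_numeric(et0, "et0")
  check_finite_numeric(kc, "kc")
  if (any(et0 < 0)) abort_input("`et0` must be >= 0.")
  if (any(kc <= 0)) abort_input("`kc` must be > 0.")
  et0 * kc
}

#' Append Kc and ETc to a daily ET0 table
#'
#' Convenience pipe step: takes the output of [calc_et0()] and adds `kc`
#' and `etc` columns for a crop.
#'
#' @param daily Tibble with `date` and `et0` columns.
#' @param crop A [crop_profile()].
#' @return `daily` with `kc` and `etc` appended.
#' @export
calc_etc <- function(daily, crop) {
  if (!all(c("date", "et0") %in% names(daily))) {
    abort_input("`daily` needs date and et0 columns (run calc_et0() first).")
  }
  daily <- as_tibble(daily)
  daily$kc <- kc_on_day(crop, daily$date)
  daily$etc <- crop_evapotranspiration(daily$et0, daily$kc)
  daily
}
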