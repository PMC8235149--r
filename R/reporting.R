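#' Seasonal irrigation total
#'
#' Sums the event volumes of an irrigation log. Accepts the output of
#' [table2_fixture()] (pick a column), a `season_sim` events table, or any
#' numeric vector of event volumes.
#'
#' @param volumes Numeric vector of per-event volumes, litres, >= 0.
#' @return Total litres.
#' @export
seasonal_totals <- function(volumes) {
  check_finite_numeric(volumes, "volumes")
  if (any(volumes < 0)) abort_input("event volumes must be >= 0.")
  sum(volumes)
}

#' Season-end totals of the Gadap field trial
#'
#' The printed season outcomes of the two 2-acre plots — water use, yield
#' and revenue — used as inputs to the comparison arithmetic. (The
#' per-event log is in [table2_fixture()]; its column sums, 96,869 L and
#' 45,218 L, differ slightly from these season totals as printed, and both
#' are surfaced without reconciliation.)
#'
#' @return A list: `water_a_l`, `water_b_l`, `yield_per_tree_a_kg`,
#'   `yield_per_tree_b_kg`, `yield_per_acre_a_kg`, `yield_per_acre_b_kg`,
#'   `revenue_a_pkr`, `revenue_b_pkr`, `trees_per_acre`,
#'   `national_area_acres`, `water_per_acre_a_l` (the per-acre figure used
#'   in the national scale-up).
#' @export
gadap_trial <- function() {
  list(
    water_a_l = 96569, water_b_l = 44290,
    yield_per_tree_a_kg = 67, yield_per_tree_b_kg = 91,
    yield_per_acre_a_kg = 4690, yield_per_acre_b_kg = 6370,
    revenue_a_pkr = 134000, revenue_b_pkr = 182000,
    trees_per_acre = 70,
    national_area_acres = 12355.27,
    water_per_acre_a_l = 96569.8, water_per_acre_b_l = 44290
  )
}

#' Compare two irrigation regimes over a season
#'
#' The trial arithmetic: water saved, the demand-driven regime's usage as a
#' percentage of the traditional one (rounded to the nearest integer for
#' the headline, one decimal alongside), and yield/revenue comparisons.
#' The yield increase is reported both truncated to an integer (as headline
#' percentages usually are) and to one decimal.
#'
#' @param water_a,water_b Seasonal water use of the traditional (A) and
#'   scheduled (B) regime, litres; `water_a` must be > 0.
#' @param yield_per_tree_a,yield_per_tree_b kg per tree (optional).
#' @param yield_per_acre_a,yield_per_acre_b kg per acre (optional).
#' @param revenue_a,revenue_b Seasonal revenue (optional).
#' @return One-row tibble (class `trial_comparison`) with columns
#'   `water_a_l`, `water_b_l`, `water_saved_l`, `percent_of_traditional`,
#'   `percent_of_traditional_1dp`, and where inputs were given
#'   `yield_increase_pct_trunc`, `yield_increase_pct_1dp`,
#'   `yield_per_acre_diff_kg`, `revenue_diff`.
#' @examples
#' t <- gadap_trial()
#' compare_trial(t$water_a_l, t$water_b_l,
#'               yield_per_tree_a = 67, yield_per_tree_b = 91,
#'               yield_per_acre_a = 4690, yield_per_acre_b = 6370)
#' @export
compare_trial <- function(water_a, water_b,
                          yield_per_tree_a = NA_real_,
                          yield_per_tree_b = NA_real_,
                          yield_per_acre_a = NA_real_,
                          yield_per_acre_b = NA_real_,
                          revenue_a = NA_real_, revenue_b = NA_real_) {
  check_finite_numeric(water_a, "water_a")
  check_finite_numeric(water_b, "water_b")
  if (water_a <= 0) abort_input("`water_a` must be > 0.")
  pct <- 100 * water_b / water_a
  out <- tibble(
    water_a_l = water_a, water_b_l = water_b,
    water_saved_l = water_a - water_b,
    percent_of_traditional = round(pct),
    percent_of_traditional_1dp = round(pct, 1)
  )
  if (!is.na(yield_per_tree_a) && !is.na(yield_per_tree_b)) {
    inc <- 100 * (yield_per_tree_b - yield_per_tree_a) / yield_per_tree_a
    out$yield_per_tree_a_kg <- yield_per_tree_a
    out$yield_per_tree_b_kg <- yield_per_tree_b
    out$yield_increase_pct_trunc <- trunc(inc)
    out$yield_increase_pct_1dp <- round(inc, 1)
  }
  if (!is.na(yield_per_acre_a) && !is.na(yield_per_acre_b)) {
    out$yield_per_acre_a_kg <- yield_per_acre_a
    out$yield_per_acre_b_kg <- yield_per_acre_b
    out$yield_per_acre_diff_kg <- yield_per_acre_b - yield_per_acre_a
  }
  if (!is.na(revenue_a) && !is.na(revenue_b)) {
    out$revenue_a <- revenue_a
    out$revenue_b <- revenue_b
    out$revenue_diff <- revenue_b - revenue_a
  }
  class(out) <- c("trial_comparison", class(out))
  out
}

#' Scale per-acre trial outcomes to a national planted area
#'
#' Multiplies per-acre yield and water figures by the planted area with no
#' intermediate rounding, reporting yield in kg and tonnes and water in
#' litres and cubic feet (28.3168 L/ft3).
#'
#' @param yield_per_acre_a,yield_per_acre_b kg/acre.
#' @param water_per_acre_a,water_per_acre_b litres/acre.
#' @param area_acres Planted area, acres. Default 12,355.27 (the national
#'   lemon area, ~5000 ha).
#' @return One-row tibble with totals and differences: `total_yield_a_kg`,
#'   `total_yield_b_kg`, `yield_diff_kg`, `total_yield_a_tons`, ...,
#'   `total_water_a_l`, `total_water_b_l`, `water_diff_l`,
#'   `total_water_a_ft3`, `total_water_b_ft3`, `water_diff_ft3`,
#'   `area_acres`.
#' @export
extrapolate_national <- function(yield_per_acre_a, yield_per_acre_b,
                                 water_per_acre_a, water_per_acre_b,
                                 area_acres = 12355.27) {
  for (v in list(yield_per_acre_a, yield_per_acre_b, water_per_acre_a,
                 water_per_acre_b, area_acres)) {
    check_finite_numeric(v, "per-acre value")
    if (v <= 0) abort_input("per-acre values and area must be > 0.")
  }
  ya <- yield_per_acre_a * area_acres
  yb <- yield_per_acre_b * area_acres
  wa <- water_per_acre_a * area_acres
  wb <- water_per_acre_b * area_acres
  tibble(
    area_acres = area_acres,
    total_yield_a_kg = ya, total_yield_b_kg = yb, yield_diff_kg = yb - ya,
    total_yield_a_tons = ya / 1000, total_yield_b_tons = yb / 1000,
    yield_diff_tons = (yb - ya) / 1000,
    total_water_a_l = wa, total_water_b_l = wb, water_diff_l = wa - wb,
    total_water_a_ft3 = wa / L_PER_FT3, total_water_b_ft3 = wb / L_PER_FT3,
    water_diff_ft3 = (wa - wb) / L_PER_FT3
  )
}
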