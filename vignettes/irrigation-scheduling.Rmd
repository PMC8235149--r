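---
title: "Turn-constrained irrigation scheduling from a daily water balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turn-constrained irrigation scheduling from a daily water balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warabandi)
```

This vignette sets out the science the package implements, the choices
made where the design was genuinely open, and what the bundled synthetic
data can and cannot tell you about real fields.

## The problem

Under Warabandi, canal water reaches a farm only on fixed turn days —
typically once a week. A scheduling decision therefore is not "irrigate
when the soil says so" but "given my next turns, must I take water on
this one?". The package couples the standard FAO-56 evapotranspiration /
water-balance machinery to that constraint for flood-irrigated orchards
in hot semi-arid conditions, where the demand side is large (daily ET0
can exceed 10 mm) and rainfall is negligible (< 240 mm/yr in the target
region; the precipitation term exists but defaults to zero).

## Reference evapotranspiration

`calc_et0()` evaluates the daily Penman–Monteith combination equation on
a grass reference surface and returns every sub-term, so any day's value
can be recomputed by hand from its own row. Conventions:

* **Soil heat flux** `G = 0` at the daily step: the diurnal heat wave
  largely cancels over 24 h.
* **Mean temperature** is `(Tmax + Tmin)/2`, and the slope Δ of the
  saturation curve is evaluated there with the Tetens coefficient
  0.6108 kPa — the same constant used in `saturation_vapor_pressure()`,
  keeping e° and its derivative consistent.
* **Vapour pressure.** The daily `e_s` is the mean of e° at the two
  temperature extremes (the curve is convex, so e°(Tmean) would bias
  low). For `e_a` the default pairing multiplies e°(Tmin) by RHmax and
  e°(Tmax) by RHmin, because RH peaks near dawn (coolest) and bottoms
  mid-afternoon (warmest); this also guarantees `e_a ≤ e_s`. A
  `pairing = "literal"` switch swaps the weights for comparison with
  data pipelines that pair same-extreme terms; it can push `e_a` above
  `e_s` on dry days, which is why it is not the default. When only a
  daily mean RH exists, `e_a = RHmean/100 · e_s` (a message notes the
  fallback).
* **Pressure and γ.** `P = 101.3 ((293 − 0.0065 z)/293)^5.26` in kPa and
  `γ = 0.665·10⁻³ P`, giving γ ≈ 0.0674 kPa/°C at sea level. All
  pressures in this package are kPa throughout.
* **Wind.** Third-party wind products report at 10 m; the log profile
  `u2 = u_z · 4.87 / ln(67.8 z − 5.42)` rescales to the 2 m reference
  level, with `z` the **measurement height above ground** (not site
  elevation — the two are easy to confuse because the same symbol is
  conventionally used for both; `site_geometry()` keeps them as separate
  fields). The default anemometer height is 10 m.
* **Net radiation** is estimated, not measured: shortwave from the
  Hargreaves temperature-range relation `R_s = k_Rs √(Tmax − Tmin) R_a`
  with `k_Rs = 0.16` (interior default; ~0.19 suits coastal advection,
  configurable), albedo 0.23, clear-sky envelope
  `R_so = (0.75 + 2·10⁻⁵ z) R_a`, and Stefan–Boltzmann longwave with
  humidity and cloudiness corrections. Two numerical guards keep the
  chain total: the sunset-hour-angle cosine is clamped to [−1, 1] so
  polar night gives `R_a = 0` exactly rather than `NaN`, and the
  relative shortwave ratio `R_s/R_so` is clipped to [0.25, 1] so the
  cloudiness factor stays bounded (at `R_a = 0` the longwave term is set
  to 0 outright). Negative raw ET0 — possible on cold overcast days — is
  floored at zero.

The suite checks the whole chain against an independent straight-line
FAO-56 transcription on 200 random physically plausible days; the two
agree to well under 0.05 mm/day (they are algebraically identical, so
the observed gap is pure floating-point noise).

## Crop coefficient and crop demand

`ETc = Kc · ET0`, with Kc a staged curve: constant in the initial and
mid stages, linear ramps through development and late stages, continuous
at the joins. The bundled lemon profile uses four stages of 60/60/90/60
days with Kc 0.65 → 0.75 → 0.75 → 0.70, inside the 0.6–0.8 band
tabulated for citrus; stage lengths are configurable because they are
site practice, not physiology. Dates past the final stage hold the last
Kc — citrus is evergreen and a season can run longer than the nominal
curve. The single-coefficient form is deliberate: a dual basal/evaporation
split needs wetting-event bookkeeping at sub-daily resolution that the
data model here (daily weather, one moisture sensor at 30 cm) cannot
support honestly; it is a possible extension, not an omission by
accident.

## Root-zone water balance

The root zone is a single bucket of plant-extractable storage
`TAW = 1000 (θ_FC − θ_WP) Z_r` mm. Depletion `D_r` (mm below field
capacity) evolves daily as ETc first, then irrigation and precipitation
— the end-of-day ("final depletion") convention, so the irrigation
trigger `D_r ≥ RAW` (boundary inclusive) is evaluated after the day's
drawdown. `RAW = p · TAW` with `p = 0.5` by default, the usual citrus
figure; an optional demand adjustment `p_eff = p + 0.04 (5 − ETc)`
clamped to [0.1, 0.8] tightens the threshold on high-demand days (off by
default — it changes the trigger day by at most ±1 in our simulations
but complicates auditability).

Two closure rules make the balance exactly conservative, which the tests
assert to 10⁻⁹ mm over 270 days:

* water pushing `D_r` below zero leaves as **deep percolation**,
  returned per-day;
* extraction stops at `TAW`: the log carries `etc_actual`, the day's ETc
  truncated by what the dry bucket could still supply, and the
  conservation identity is stated on `etc_actual`. (No stress-reduction
  function is applied between RAW and TAW; a scheduled field should
  never be there, and when it is, the honest statement is "unmet
  demand", not a modelled reduction.)

When hourly soil-moisture telemetry is available, each day's initial
depletion is re-anchored from the daily mean θ via
`D_r = 1000 (θ_FC − θ_mean) Z_r` before the fluxes apply, so sensor
drift cannot accumulate; without telemetry the bookkeeping simply
carries over. With a noise-free simulated sensor the two modes agree
exactly, which is a designed identity (see below), not a coincidence.

## The turn-constrained scheduler

`forecast_need_date()` projects depletion at the mean of the last
`k = 3` days' ETc (persistence). Demand at this site is strongly
autocorrelated day-to-day, and a 3-day mean filters single-day noise
without lagging the seasonal ramp; `k` is an argument, not a constant.
The need date is the first day the projection reaches RAW (an epsilon of
10⁻⁹ guards the ceiling against float noise — without it, RAW values
that arrive via YAML round-off can shift the date by a day).
`align_to_turn()` then takes the **latest turn on or before** the need
date: watering early wastes little (the refill is sized to the actual
deficit) while watering late risks stress. If that turn is already past,
the next turn is recommended with an explicit `missed_turn` flag rather
than silently, since the crop may cross RAW in between.

The recommended depth is the depletion projected at the end of the turn
date (refill to field capacity) — not today's depletion, because the
crop keeps transpiring until the turn; a `depth_at = "current"` switch
exists for comparison. Volume, run time and acre-inches are exact unit
identities on that depth (1 mm·m² = 1 L; 102,790.15 L per acre-inch,
fixed to two decimals so round-trips are bit-exact), so the same water
is delivered whichever unit the farmer prefers.

`simulate_season()` closes the loop. On each turn day the demand-driven
policy projects end-of-day depletion for today and every day strictly
before the next turn and irrigates now if any projection reaches RAW
(the next turn can protect itself, so it is excluded). The comparison
policy floods a fixed gross depth — default 60 mm, a typical basin
application comfortably above peak weekly demand — on **every** turn,
the way the traditional plots in the underlying trial were farmed;
surplus above the deficit percolates. This asymmetry matters for the
water comparison: if both policies applied exact net refills, seasonal
totals would be pinned by mass balance to differ only through the
end-of-season state, and the comparison would say nothing. With the
realistic gross-application baseline, the demand-driven policy's saving
comes from skipped turns *and* avoided percolation, which is the
mechanism the trial observed.

## The synthetic season generator

`generate_weather_season()` produces seeded daily weather: a sinusoidal
annual cycle in daily mean temperature peaking at day-of-year 166, a
fixed diurnal range split around it, RH anti-correlated with the
seasonal temperature anomaly (−1.5 %/°C), folded-Gaussian wind at 10 m,
and independent Gaussian noise per channel from one seed. The
`karachi_season_spec()` preset (mean 29 °C, seasonal half-range 11 °C,
diurnal range 16 °C, RH base 55 %, wind 3.5 m/s, 270 days from
1 February) was set from the trial region's climate before any tests
were written: its deterministic summer peak puts daily maxima at 48 °C,
and noise carries individual days into the low 50s, matching a site
whose sensors recorded 52 °C.

`simulate_sensor()` emits hourly telemetry with a deliberate identity:
within each day θ declines with the day's ETc over hours 0–17 and sits
at the bookkeeping end-of-day level from 18:00 (an evening turn), with
the morning segment centred so the 24-h mean inverts *exactly* to the
day's initial depletion. That makes "sensor-anchored equals bookkeeping
when noise-free" a provable property the tests assert to 10⁻⁹ mm, and
makes noisy-sensor experiments interpretable (any divergence is the
noise, not the construction). Clipping to the physical range
[0.8 θ_WP, θ_FC] can perturb the mean on days that touch the bounds.

What the generator does **not** emulate: weather spell persistence
(every day is conditionally independent), humidity–temperature coupling
beyond the seasonal term, advective heat waves, rainfall, sensor drift
and dropout, or spatial variability. Passing tests on this data
establish the *internal* correctness of the chain — conservation,
trigger logic, turn alignment, determinism — not predictive skill on any
real farm; the trial's own season totals enter the package only as
recorded inputs to the comparison arithmetic, never as model output.

## Reporting arithmetic

`compare_trial()` and `extrapolate_national()` reproduce the trial's
season-total comparisons from printed inputs with no intermediate
rounding: water saved, usage as a rounded percentage of traditional,
yield increase both truncated (headline style) and to one decimal, and
per-acre × national-area products. Two recorded inconsistencies are
surfaced rather than reconciled: the per-event log (`table2_fixture()`)
sums to 96,869 / 45,218 L while the season-total table says
96,569 / 44,290 L (the totals are treated as canonical, the log is
provided as-is); and the trial's cubic-foot column is not consistent
with a single conversion factor, so cubic feet here are always
litres / 28.3168.

## Problem sizes and determinism

The test suite simulates 270-day seasons (the trial's 9 months), 200-day
oracle sweeps and 20–90-day targeted scenarios; everything runs in a few
seconds on one core. All stochastic paths take explicit integer seeds,
and `run_season()` writes byte-identical logs on reruns with the same
config — determinism is asserted at the file level, not just the value
level.

## Known limitations

Single-layer bucket (no capillary rise, runoff or salinity), single
field and single farmer (no multi-user water-rights optimisation),
single-coefficient Kc, estimated rather than measured radiation, and a
persistence ETc forecast that will lag abrupt weather changes by a day
or two. Each is the simplest defensible choice for the data a low-cost
node actually provides; the module boundaries are drawn so any of them
can be upgraded without touching the rest.
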