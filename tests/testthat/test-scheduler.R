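test_that("need-date forecast uses the trailing-mean ETc rate", {
  mk <- function(dr) water_balance_state("2018-06-04", dr, 220, 110) # a Monday
  # already triggered: today
  expect_equal(forecast_need_date(mk(110), recent_etc = c(5, 5, 5)),
               as.Date("2018-06-04"))
  # ceiling((110 - 100) / 5) = 2 days out
  expect_equal(forecast_need_date(mk(100), recent_etc = c(5, 5, 5)),
               as.Date("2018-06-06"))
  # only the last k values count
  expect_equal(forecast_need_date(mk(100), recent_etc = c(99, 5, 5, 5), k = 3),
               as.Date("2018-06-06"))
  # zero demand: never within the horizon
  expect_true(is.na(forecast_need_date(mk(50), recent_etc = c(0, 0))))
  expect_error(forecast_need_date(mk(50), recent_etc = numeric(0)),
               class = "warabandi_invalid_input")
})

test_that("turn alignment picks the latest turn on or before the need date", {
  fridays <- warabandi_calendar(as.Date("2018-06-01"), period_days = 7)
  # a turn day aligns to itself
  expect_equal(align_to_turn(as.Date("2018-06-08"), fridays),
               as.Date("2018-06-08"))
  # need on Monday 11 June -> previous Friday 8 June
  expect_equal(align_to_turn(as.Date("2018-06-11"), fridays),
               as.Date("2018-06-08"))
  explicit <- warabandi_calendar(turn_dates = as.Date("2018-06-01") + c(0, 4, 8))
  expect_equal(align_to_turn(as.Date("2018-06-07"), explicit),
               as.Date("2018-06-05"))
  expect_error(align_to_turn(as.Date("2018-05-01"), explicit),
               class = "warabandi_no_feasible_turn")
})

test_that("recommendations carry mutually consistent output units", {
  cal <- warabandi_calendar(as.Date("2018-06-01"), period_days = 7)
  flow <- flow_spec(flow_rate = 100, field_area = 1000)
  st <- water_balance_state("2018-06-08", 105, 220, 110) # turn day, near RAW
  rec <- recommend(st, recent_etc = c(5, 5, 5), calendar = cal, flow = flow)
  expect_s3_class(rec, "irrigation_recommendation")
  expect_lte(rec$turn_date, rec$need_date)
  expect_equal(rec$volume_l, rec$depth_mm * 1000)
  expect_equal(rec$duration_min, rec$volume_l / 100)
  expect_equal(rec$acre_inches, rec$volume_l / 102790.15)
  # no projected need -> no recommendation
  expect_null(recommend(water_balance_state("2018-06-08", 0, 220, 110),
                        recent_etc = c(0, 0, 0), calendar = cal, flow = flow))
  # aligned turn already past -> next turn plus a stress warning
  st_missed <- water_balance_state("2018-06-09", 108, 220, 110) # Saturday
  expect_warning(
    rec2 <- recommend(st_missed, recent_etc = c(5, 5, 5), calendar = cal,
                      flow = flow),
    "next turn"
  )
  expect_true(rec2$missed_turn)
  expect_equal(rec2$turn_date, as.Date("2018-06-15"))
})

test_that("output-unit conversions are exact identities", {
  flow <- flow_spec(flow_rate = 1, field_area = 1000)
  expect_equal(convert_output(0, flow, "volume"), 0)
  expect_equal(convert_output(0, flow, "time"), 0)
  expect_equal(convert_output(0, flow, "acre_inch"), 0)
  # 5 L at 1 L/min runs 5 minutes
  expect_equal(convert_output(5, flow, "time"), 5)
  expect_equal(convert_output(5000, flow, "acre_inch"), 0.04864,
               tolerance = 1e-4 / 0.04864)
  # round trips
  for (u in c("volume", "time", "acre_inch")) {
    expect_equal(output_to_volume(convert_output(1234.5, flow, u), flow, u),
                 1234.5, tolerance = 1e-6)
  }
  expect_error(convert_output(5, flow, "bushels"),
               class = "warabandi_invalid_input")
})

test_that("season under the demand-driven policy respects the turn calendar", {
  s <- default_setup(seed = 6)
  weather <- generate_weather_season(s$spec)
  sim <- simulate_season(weather, s$site, s$crop, s$soil, s$calendar,
                         s$flow, policy = "dss")
  d <- sim$daily
  # irrigation only on turn days
  expect_true(all(d$turn_day[d$irrigation > 0]))
  # depletion bounded by storage
  expect_true(all(d$dr_final >= 0 & d$dr_final <= d$taw))
})

test_that("perfect foresight keeps depletion at or below RAW all season", {
  s <- default_setup(seed = 8)
  weather <- generate_weather_season(s$spec)
  sim <- simulate_season(weather, s$site, s$crop, s$soil, s$calendar,
                         s$flow, policy = "dss", foresight = TRUE)
  expect_true(all(sim$daily$dr_final <= sim$params$raw + 1e-9))
})

test_that("the demand-driven policy uses strictly less water than irrigating every turn", {
  s <- default_setup(seed = 10)
  weather <- generate_weather_season(s$spec)
  dss <- simulate_season(weather, s$site, s$crop, s$soil, s$calendar,
                         s$flow, policy = "dss")
  fixed <- simulate_season(weather, s$site, s$crop, s$soil, s$calendar,
                           s$flow, policy = "every_turn")
  expect_lt(sum(dss$events$volume_l), sum(fixed$events$volume_l))
  expect_lt(nrow(dss$events), nrow(fixed$events))
})
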