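test_that("seasonal totals sum event volumes", {
  expect_equal(seasonal_totals(numeric(0)), 0)
  expect_equal(seasonal_totals(5000), 5000)
  t2 <- table2_fixture()
  expect_equal(seasonal_totals(t2$area_b_l), 45218)
  expect_equal(seasonal_totals(t2$area_a_l), 96869)
  expect_error(seasonal_totals(c(10, -1)), class = "warabandi_invalid_input")
})

test_that("trial comparison reproduces the season-total arithmetic", {
  t <- gadap_trial()
  cmp <- compare_trial(t$water_a_l, t$water_b_l,
                       yield_per_tree_a = t$yield_per_tree_a_kg,
                       yield_per_tree_b = t$yield_per_tree_b_kg,
                       yield_per_acre_a = t$yield_per_acre_a_kg,
                       yield_per_acre_b = t$yield_per_acre_b_kg,
                       revenue_a = t$revenue_a_pkr,
                       revenue_b = t$revenue_b_pkr)
  expect_equal(cmp$water_saved_l, 52279)
  expect_equal(cmp$percent_of_traditional, 46)
  expect_equal(cmp$percent_of_traditional_1dp, 45.9)
  expect_equal(cmp$yield_increase_pct_trunc, 35)
  expect_equal(cmp$yield_increase_pct_1dp, 35.8)
  expect_equal(cmp$yield_per_acre_diff_kg, 1680)
  expect_equal(cmp$revenue_diff, 48000)
  # degenerate cases
  eq <- compare_trial(1000, 1000)
  expect_equal(eq$water_saved_l, 0)
  expect_equal(eq$percent_of_traditional, 100)
  expect_error(compare_trial(0, 10), class = "warabandi_invalid_input")
})

test_that("national extrapolation is an exact product with no intermediate rounding", {
  t <- gadap_trial()
  ext <- extrapolate_national(t$yield_per_acre_a_kg, t$yield_per_acre_b_kg,
                              t$water_per_acre_a_l, t$water_per_acre_b_l)
  expect_equal(ext$total_yield_a_kg, 57946216.3)
  expect_equal(ext$total_yield_b_kg, 78703069.9)
  expect_equal(ext$water_diff_l, 645931044.546)
  expect_equal(ext$total_yield_a_tons, ext$total_yield_a_kg / 1000)
  expect_equal(ext$water_diff_ft3, ext$water_diff_l / 28.3168)
  # unit area is the identity
  id <- extrapolate_national(4690, 6370, 96569.8, 44290, area_acres = 1)
  expect_equal(id$total_yield_a_kg, 4690)
  expect_equal(id$total_water_b_l, 44290)
})

test_that("config example round-trips through the reader", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config_example(path)
  cfg <- read_config(path)
  expect_s3_class(cfg$site, "site_geometry")
  expect_equal(cfg$site$latitude, 24.9)
  expect_equal(cfg$crop$crop_name, "lemon")
  expect_equal(nrow(cfg$crop$stages), 4)
  expect_equal(cfg$soil$theta_fc, 0.32)
  expect_equal(cfg$calendar$period_days, 7)
  expect_equal(cfg$flow$flow_rate, 200)
  expect_equal(cfg$season$n_days, 270)
  expect_equal(cfg$options$ea_pairing, "fao")
})

test_that("malformed configs fail with a parse error naming the problem", {
  p1 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("site:\n  latitude: 24.9", p1)
  expect_error(read_config(p1), "lacks section",
               class = "warabandi_parse_error")
  p2 <- withr::local_tempfile(fileext = ".yaml")
  write_config_example(p2)
  writeLines(c(readLines(p2), "bogus_section:", "  a: 1"), p2)
  expect_error(read_config(p2), "unknown config section",
               class = "warabandi_parse_error")
})

test_that("a configured season run writes logs and is byte-identical under a fixed seed", {
  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  write_config_example(cfg_path)
  cfg <- read_config(cfg_path)
  cfg$season$n_days <- 90L

  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  r1 <- run_season(cfg, out_dir = out1)
  r2 <- run_season(cfg, out_dir = out2)
  for (f in c("daily_state.csv", "recommendations.csv", "summary.txt")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  expect_s3_class(r1$sim, "season_sim")
  expect_s3_class(r1$comparison, "trial_comparison")
  # demand-driven run uses no more water than the every-turn comparison
  expect_lte(r1$comparison$water_b_l, r1$comparison$water_a_l)
})

test_that("a zero-demand season yields no irrigation events", {
  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  write_config_example(cfg_path)
  cfg <- read_config(cfg_path)
  # cool, saturated, still and rangeless: both Penman-Monteith forcing terms
  # collapse, leaving at most a sliver of ET from the longwave correction
  cfg$season <- season_spec("2018-02-01", 60, t_mean_annual = 10,
                            t_amplitude = 0, diurnal_range = 0, rh_base = 90,
                            wind_mean = 0,
                            noise_sd = list(temp = 0, rh = 0, wind = 0),
                            random_seed = 1)
  res <- run_season(cfg, compare_every_turn = FALSE)
  expect_lt(sum(res$sim$daily$etc), 1)
  expect_equal(nrow(res$sim$events), 0)
})

test_that("tidy and glance expose the season log and its summary", {
  s <- default_setup(seed = 12)
  sim <- simulate_season(generate_weather_season(
    season_spec(s$spec$start_date, 60, random_seed = 12)),
    s$site, s$crop, s$soil, s$calendar, s$flow)
  td <- tidy(sim)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 60)
  g <- glance(sim)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_events, nrow(sim$events))
  expect_equal(g$total_volume_l, sum(sim$events$volume_l))
})

test_that("season plots build without error", {
  s <- default_setup(seed = 13)
  sim <- simulate_season(generate_weather_season(
    season_spec(s$spec$start_date, 40, random_seed = 13)),
    s$site, s$crop, s$soil, s$calendar, s$flow)
  expect_s3_class(ggplot2::autoplot(sim), "ggplot")
  expect_s3_class(plot_et_series(sim), "ggplot")
  expect_s3_class(plot_water_use(list(dss = sim)), "ggplot")
})
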