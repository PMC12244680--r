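test_that("a zero-rain year produces no yield and universal grape failure", {
  dry <- climate_series(rep(1, 365), 1:365, rep(0, 365), rep(3, 365))
  cfg <- small_config(years = 1)
  run <- run_simulation(cfg, climate = dry, seed = 2)
  expect_true(all(run$terraces$yield_kg == 0))
  expect_equal(run$annual$wine_l, 0)
  expect_true(all(run$farms$outcome_grape == "failure"))
})

test_that("identical seeds replay the simulation byte for byte", {
  cfg <- small_config(years = 5)
  a <- run_simulation(cfg, seed = 7)
  b <- run_simulation(cfg, seed = 7)
  expect_identical(a$terraces, b$terraces)
  expect_identical(a$farms, b$farms)
  expect_identical(a$annual, b$annual)
  c <- run_simulation(cfg, seed = 8)
  expect_false(identical(a$annual, c$annual))
})

test_that("basin aggregates equal independently re-summed constituents", {
  cfg <- small_config(years = 6)
  run <- run_simulation(cfg, seed = 3)
  tr <- run$terraces
  for (y in unique(tr$year)) {
    g <- sum(tr$yield_kg[tr$year == y & tr$crop == "grape"])
    expect_equal(run$annual$grape_kg[run$annual$year == y], g, tolerance = 1e-9)
    expect_equal(run$annual$wine_l[run$annual$year == y],
                 wine_volume(g, cfg$yield$wine_l_per_kg), tolerance = 1e-9)
  }
  wp <- annual_wine_production(run)
  expect_equal(length(wp), 6)
  expect_equal(unname(wp), run$annual$wine_l)
})

test_that("water, wheat and terrace ledgers close every simulated year", {
  cfg <- sim_config(years = 20)
  run <- run_simulation(cfg, seed = 5)
  an <- run$annual
  water_err <- an$water_inflow_mm - an$water_evaporation_mm -
    an$water_infiltration_mm - an$water_outlet_loss_mm - an$water_delta_storage_mm
  expect_lt(max(abs(water_err)), 1e-9)
  expect_lt(max(abs(an$wheat_balance_error_kg)), 1e-9)

  # terrace count ledger: totals only grow, by at most one expansion per farm
  n_by_year <- tapply(run$terraces$terrace, run$terraces$year, length)
  expect_true(all(diff(n_by_year) >= 0))
  expect_true(all(diff(n_by_year) <= cfg$n_farms * cfg$expansion_step))

  # no farm expands while risk-locked
  fa <- run$farms
  expect_false(any(fa$action == "expand_vineyard" &
                     fa$consec_failures >= cfg$f_max))
})

test_that("inactive terraces supply no yield the following season", {
  cfg <- small_config(years = 8, initial_storage_kg = 40, storage_cap_kg = 400)
  run <- run_simulation(cfg, seed = 13)
  tr <- run$terraces
  expect_true(all(tr$yield_kg[!tr$active] == 0))
  # young vines (establishment period) also bear nothing
  expect_true(all(tr$yield_kg[tr$crop == "grape" & !tr$mature] == 0))
})

test_that("configuration is validated and round-trips through YAML", {
  expect_error(sim_config(not_a_key = 1), "unknown configuration keys")
  expect_error(sim_config(years = 0), "years")
  cfg <- sim_config(runoff_ratio = 25, price_ratio = 0.4,
                    yield = yield_params(wine_l_per_kg = 0.7))
  p <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, p)
  back <- read_config(p)
  expect_equal(back$runoff_ratio, 25)
  expect_equal(back$price_ratio, 0.4)
  expect_equal(back$yield$wine_l_per_kg, 0.7)
  expect_equal(back$cn_table, cfg$cn_table)
  expect_equal(back$labor$vine_establish, 33.3)
})

test_that("sanity limit: benign economics yield abundant stable production", {
  # no pests, free labor, no droughts: production tracks water alone and the
  # cumulative total grows monotonically
  lab <- labor_table(
    terrace_build = 0, wheat_field_create = 0, runoff_clear = 0,
    wheat_season = 0, wheat_seed = 0, vine_establish = 0,
    vine_young_upkeep = 0, vine_mature_upkeep = 0, maintenance_rate = 0
  )
  cfg <- small_config(years = 6, labor = lab,
                      yield = yield_params(pest_penalty = 0),
                      initial_storage_kg = 1000)
  wet <- make_synthetic_climate(seed = 2, n_years = 6, annual_mean_mm = 150)
  run <- run_simulation(cfg, climate = wet, seed = 2)
  expect_true(all(run$annual$n_active_grape >= cfg$n_farms * cfg$grape_per_farm))
  expect_true(all(diff(cumsum(run$annual$wine_l)) >= 0))
})
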