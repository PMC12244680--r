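test_that("SCS-CN runoff matches the closed form and its limits", {
  # p = 4 mm at CN 92: initial abstraction (~4.42 mm) swallows the event
  expect_equal(scs_runoff(4, 92), 0)
  # impervious limit: CN 100 gives S = 0 and q = p
  expect_equal(scs_runoff(c(0.5, 7, 31), 100), c(0.5, 7, 31))
  # hand evaluation: p = 30, CN 92 -> S = 22.087, Ia = 4.417, q ~ 13.73
  s <- 25400 / 92 - 254
  ia <- 0.2 * s
  expect_equal(scs_runoff(30, 92), (30 - ia)^2 / (30 - ia + s))
  expect_equal(scs_runoff(30, 92), 13.73, tolerance = 1e-3)
  expect_error(scs_runoff(-1, 92), "negative")
  expect_error(scs_runoff(10, 0), "curve number")
})

test_that("runoff is bounded and monotone in depth and curve number", {
  ps <- with_seed(10, stats::runif(300, 0, 80))
  cns <- with_seed(11, stats::runif(300, 35, 99))
  q <- scs_runoff(ps, cns)
  expect_true(all(q >= 0 & q <= ps))
  expect_true(all(diff(scs_runoff(seq(0, 60, by = 0.5), 85)) >= 0))
  expect_true(all(diff(scs_runoff(25, seq(40, 100, by = 0.5))) >= 0))
})

test_that("cell runoff applies calibration and mound factors exactly", {
  prm <- cn_params()
  p <- 25
  expect_equal(cell_runoff(p, 85, mounds = TRUE, prm) /
                 cell_runoff(p, 85, mounds = FALSE, prm), 1.3)
  # calibration factor scales SCS runoff directly: 10 mm -> 15.67 mm
  prm2 <- cn_params(calibration_factor = 1.567)
  q0 <- scs_runoff(p, 92, prm2$lambda)
  expect_equal(cell_runoff(p, 92, FALSE, prm2), 1.567 * q0)
  expect_equal(1.567 * 10, 15.67)
  expect_equal(cell_runoff(0, 77, TRUE, prm), 0)
  expect_error(cn_params(cn_table = c(R = 101)), "curve numbers")
  expect_error(cn_params(lambda = 0.7), "lambda")
})

test_that("calibration factor is the total-volume ratio", {
  expect_equal(fit_calibration_factor(c(3, 5, 9), c(3, 5, 9)), 1)
  sim <- c(2.2, 8, 1.5, 30)
  expect_equal(fit_calibration_factor(sim, 1.567 * sim), 1.567)
  obs <- c(4, 2, 11, 28)
  expect_equal(fit_calibration_factor(sim, obs), sum(obs) / sum(sim))
  expect_error(fit_calibration_factor(numeric(0), numeric(0)), "n >= 1")
  expect_error(fit_calibration_factor(c(1, -1), c(1, 1)), "positive")
})

test_that("daily step conserves water and follows the operation order", {
  ws <- small_watershed()
  lu <- assign_land_use(ws, runoff_ratio = 10, n_farms = 2, grape_per_farm = 1,
                        wheat_per_farm = 1, reserve_sites = 0)
  basin <- compile_basin(ws, lu)
  st <- water_state(basin)

  # null day on dry terraces changes nothing
  out <- daily_step(basin, st, 0, 0)
  expect_identical(out$state$column, st$column)
  expect_identical(out$state$accum, st$accum)
  expect_equal(unname(out$ledger["inflow"]), 0)

  # catchment-free terrace: accumulator gains min(p - e, i) exactly
  lone <- basin
  lone$coef[] <- 0
  o1 <- daily_step(lone, water_state(lone), 10, 2)
  expect_equal(o1$state$accum, pmin(10 - 2, lone$infil))

  # heavy storm overflows at capacity and the ledger closes to 1e-9 mm
  st2 <- water_state(basin)
  led_sum <- c(inflow = 0, evaporation = 0, infiltration = 0, outlet_loss = 0)
  for (p in c(60, 45, 0, 30, 0, 0)) {
    o <- daily_step(basin, st2, p, 3)
    st2 <- o$state
    expect_equal(
      unname(o$ledger["inflow"]),
      unname(o$ledger["evaporation"] + o$ledger["infiltration"] +
               o$ledger["outlet_loss"] + o$ledger["delta_storage"]),
      tolerance = 1e-9
    )
    expect_true(all(st2$column <= basin$capacity + 1e-9))
    led_sum <- led_sum + o$ledger[names(led_sum)]
  }
  expect_gt(unname(led_sum["outlet_loss"]) + sum(st2$column), 0)
  expect_error(daily_step(basin, st2, -1, 0), "negative")
})

test_that("seasonal accumulator equals the day-by-day infiltration ledger", {
  ws <- small_watershed()
  lu <- assign_land_use(ws, runoff_ratio = 10, n_farms = 2, grape_per_farm = 1,
                        wheat_per_farm = 1, reserve_sites = 0)
  basin <- compile_basin(ws, lu)
  st <- water_state(basin)
  p <- with_seed(3, ifelse(stats::runif(80) < 0.15, stats::rgamma(80, 0.6, scale = 9), 0))
  infil_ledger <- numeric(basin$n_terraces)
  for (d in seq_along(p)) {
    before <- st$accum
    o <- daily_step(basin, st, p[d], 2.5)
    st <- o$state
    infil_ledger <- infil_ledger + (st$accum - before)
  }
  saw <- seasonal_available_water(st)
  expect_equal(saw$available_mm, infil_ledger, tolerance = 1e-12)
  expect_equal(saw$state$accum, numeric(basin$n_terraces))

  # zero-rain season yields zero available water everywhere
  st0 <- water_state(basin)
  for (d in 1:30) st0 <- daily_step(basin, st0, 0, 3)$state
  expect_equal(seasonal_available_water(st0)$available_mm,
               numeric(basin$n_terraces))
})

test_that("higher runoff ratios never harvest less seasonal water", {
  ws <- small_watershed()
  cl <- make_synthetic_climate(seed = 17, n_years = 4)
  waters <- sapply(c(5, 30), function(r) {
    lu <- assign_land_use(ws, runoff_ratio = r, n_farms = 2,
                          grape_per_farm = 1, wheat_per_farm = 1,
                          reserve_sites = 0)
    cfg <- small_config(years = 4, runoff_ratio = r)
    run <- run_simulation(cfg, ws, cl, landuse = lu, seed = 1)
    tr <- run$terraces
    mean(tr$water_mm[tr$crop == "grape"])
  })
  expect_gt(waters[2], waters[1])

  # doubling every daily depth never decreases harvested water
  cl2 <- cl
  cl2$precip_mm <- cl2$precip_mm * 2
  lu <- assign_land_use(ws, runoff_ratio = 10, n_farms = 2, grape_per_farm = 1,
                        wheat_per_farm = 1, reserve_sites = 0)
  cfg <- small_config(years = 4)
  w1 <- run_simulation(cfg, ws, cl, landuse = lu, seed = 1)$terraces$water_mm
  w2 <- run_simulation(cfg, ws, cl2, landuse = lu, seed = 1)$terraces$water_mm
  expect_true(all(w2 >= w1 - 1e-9))
})
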