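test_that("climate series validation and drought classification boundaries", {
  zeros <- climate_series(rep(1, 365), 1:365, rep(0, 365), rep(3, 365))
  expect_equal(unname(annual_totals(zeros)), 0)
  expect_true(unname(classify_drought_years(zeros)[1]))

  expect_error(climate_series(rep(1, 364), 1:364, rep(0, 364), rep(3, 364)),
               "365")
  expect_error(climate_series(rep(1, 365), 1:365, rep(-1, 365), rep(3, 365)),
               "negative")

  # strict threshold: 65.9 mm is a drought year, 66.0 mm is not
  mk <- function(total) {
    p <- rep(0, 365)
    p[50] <- total
    climate_series(rep(1, 365), 1:365, p, rep(3, 365))
  }
  expect_true(unname(classify_drought_years(mk(65.9))[1]))
  expect_false(unname(classify_drought_years(mk(66.0))[1]))
})

test_that("climate CSV round-trips, drops Feb-29 and names missing days", {
  cl <- make_synthetic_climate(seed = 3, n_years = 2)
  p <- withr::local_tempfile(fileext = ".csv")
  write_climate_csv(cl, p)
  back <- read_climate_csv(p)
  expect_equal(back$precip_mm, cl$precip_mm)
  expect_equal(back$evap_mm, cl$evap_mm)
  expect_equal(back$year, cl$year)

  # drop a single calendar day: the error names the date
  df <- utils::read.csv(p)
  utils::write.csv(df[-100, ], p, row.names = FALSE, quote = FALSE)
  expect_error(read_climate_csv(p), df$date[100])

  # only temperature present: evaporation is synthesized via the transfer
  p <- withr::local_tempfile(fileext = ".csv")
  write_climate_csv(cl, p)
  df2 <- utils::read.csv(p)
  df2$evap_mm <- NULL
  utils::write.csv(df2, p, row.names = FALSE, quote = FALSE)
  back2 <- read_climate_csv(p, evap_coeffs = c(a = 0.35, b = -1.5))
  expect_equal(back2$evap_mm, temp_to_evaporation(cl$tmean_c), tolerance = 1e-12)

  df2$precip_mm[5] <- -2
  utils::write.csv(df2, p, row.names = FALSE, quote = FALSE)
  expect_error(read_climate_csv(p), "row 5")
})

test_that("gap filling recovers the inter-station linear map", {
  n <- 730
  ref <- data.frame(precip_mm = with_seed(1, stats::rgamma(n, 0.5, scale = 8)))
  # self-fill: slope 1, intercept 0, perfect correlation, zero deviation
  tgt <- ref
  tgt$precip_mm[100:150] <- NA
  fit <- gap_fill_by_regression(tgt, ref)
  expect_equal(fit$report$slope, 1, tolerance = 1e-9)
  expect_equal(fit$report$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$report$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$report$deviation_pct, 0, tolerance = 1e-9)
  expect_equal(fit$filled$precip_mm, ref$precip_mm, tolerance = 1e-9)

  # reference scaled by 2 with no noise: recovered slope 0.5, filled exact
  ref2 <- data.frame(precip_mm = 2 * ref$precip_mm)
  tgt2 <- ref
  tgt2$precip_mm[1:50] <- NA
  fit2 <- gap_fill_by_regression(tgt2, ref2)
  expect_equal(fit2$report$slope, 0.5, tolerance = 1e-9)
  expect_equal(fit2$filled$precip_mm[1:50], ref$precip_mm[1:50], tolerance = 1e-9)

  # noisy pair: reported R^2 matches an independent correlation computation
  noise <- with_seed(2, stats::rnorm(n, 0, 1))
  tgt3 <- data.frame(precip_mm = pmax(0, 0.8 * ref$precip_mm + noise))
  tgt3$precip_mm[200:260] <- NA
  fit3 <- gap_fill_by_regression(tgt3, ref)
  ok <- !is.na(tgt3$precip_mm)
  expect_equal(fit3$report$r_squared,
               stats::cor(tgt3$precip_mm[ok], ref$precip_mm[ok])^2,
               tolerance = 1e-9)

  expect_error(gap_fill_by_regression(tgt[1:20, , drop = FALSE],
                                      ref[1:20, , drop = FALSE]),
               "overlap")
})

test_that("temperature-evaporation transfer is linear with clamping", {
  expect_equal(temp_to_evaporation(c(-10, 0, 40), c(a = 0, b = 5)),
               c(5, 5, 5))
  # temperatures below -b/a clamp to zero evaporation
  expect_equal(temp_to_evaporation(-20, c(a = 0.3, b = 1)), 0)
  # coefficient recovery from noiseless paired data
  t <- seq(2, 35, length.out = 200)
  e <- 0.3 * t + 1
  fit <- fit_evaporation_coeffs(t, e)
  expect_equal(fit$a, 0.3, tolerance = 1e-6)
  expect_equal(fit$b, 1, tolerance = 1e-6)
  expect_error(temp_to_evaporation(c(1, NA)), "temperature")
})

test_that("drought injection rescales only the window, multiplicatively", {
  cl <- make_synthetic_climate(seed = 8, n_years = 10)
  expect_identical(inject_drought(cl, 3, 0), cl)

  out <- inject_drought(cl, 3, 5, seed = 99)
  tot <- annual_totals(out)
  expect_true(all(tot[3:7] < 66))
  expect_true(all(tot[3:7] >= 0.5 * 66 - 1e-9))
  # untouched years are bitwise identical
  keep <- out$year %in% c(1, 2, 8, 9, 10)
  expect_identical(out$precip_mm[keep], cl$precip_mm[keep])
  # within a drought year every day scales by the same ratio
  for (yy in 3:7) {
    sel <- cl$year == yy
    ratio <- sum(out$precip_mm[sel]) / sum(cl$precip_mm[sel])
    expect_equal(out$precip_mm[sel], cl$precip_mm[sel] * ratio,
                 tolerance = 1e-12)
  }
  # idempotence outside the window under repeated injection
  out2 <- inject_drought(out, 3, 5, seed = 99)
  expect_identical(out2$precip_mm[keep], cl$precip_mm[keep])

  expect_error(inject_drought(cl, 9, 4), "window")
  expect_error(inject_drought(cl, 1, 9), "0..5")
})

test_that("wetter scaling is exact and commutes with annual summation", {
  cl <- make_synthetic_climate(seed = 4, n_years = 5)
  expect_equal(scale_wetter(cl, 1)$precip_mm, cl$precip_mm)
  out <- scale_wetter(cl, 1.25)
  expect_equal(annual_totals(out), annual_totals(cl) * 1.25, tolerance = 1e-12)
  expect_equal(out$evap_mm, cl$evap_mm)
  expect_equal(87 * 1.25, 108.75)
  expect_error(scale_wetter(cl, 0.9), ">= 1")
})

test_that("synthetic climate matches its calibrated desert statistics", {
  a <- make_synthetic_climate(seed = 5, n_years = 3)
  b <- make_synthetic_climate(seed = 5, n_years = 3)
  expect_identical(a, b)
  expect_error(make_synthetic_climate(seed = 1, n_years = 0), "n_years")

  cl <- make_synthetic_climate(seed = 31, n_years = 200)
  tot <- annual_totals(cl)
  expect_gt(mean(tot), 78)
  expect_lt(mean(tot), 96)
  freq <- mean(tot < 66)
  expect_gt(freq, 0.27)
  expect_lt(freq, 0.47)
  # rain is winter-concentrated: nothing falls outside the wet season
  expect_true(all(cl$precip_mm[cl$day > 210] == 0))
  expect_true(all(cl$evap_mm >= 0))
})

test_that("year resampling builds aligned horizons from a library", {
  lib <- make_synthetic_climate(seed = 21, n_years = 30)
  dec <- sample_years(lib, 10, seed = 3)
  expect_s3_class(dec, "af_climate")
  expect_equal(nrow(dec), 3650)
  expect_equal(unique(dec$year), 1:10)
  # every assembled year is a verbatim copy of some library year
  lib_tot <- round(unname(annual_totals(lib)), 9)
  expect_true(all(round(unname(annual_totals(dec)), 9) %in% lib_tot))
  # fixed positions draw from the non-drought pool
  hz <- sample_years(lib, 20, seed = 3, fixed_years = 1:5)
  expect_true(all(unname(annual_totals(hz))[1:5] >= 66))
  # reproducible
  expect_identical(sample_years(lib, 10, seed = 3), dec)
})
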