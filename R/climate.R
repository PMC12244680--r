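# Daily climate series: CSV ingestion, gap filling, temperature-to-evaporation
# transfer, drought classification and scenario transforms, plus a synthetic
# desert-climate generator.
#
# A model year is exactly 365 ticks (days). Day 1 of each year is the start of
# the hydrological year (nominally October 1), so the whole wet season falls
# inside one model year and the annual harvest closes at day 365.

#' Construct a daily climate series
#'
#' @param year Integer year id per row.
#' @param day Day-of-year 1..365.
#' @param precip_mm Daily precipitation (mm, >= 0).
#' @param evap_mm Daily free-water evaporation (mm, >= 0).
#' @param tmean_c Optional daily mean temperature (deg C).
#' @return A data.frame of class `af_climate`.
#' @export
climate_series <- function(year, day, precip_mm, evap_mm, tmean_c = NULL) {
  n <- length(year)
  if (length(day) != n || length(precip_mm) != n || length(evap_mm) != n) {
    stop_af("climate columns must have equal length")
  }
  if (any(precip_mm < 0, na.rm = TRUE)) stop_af("negative precipitation")
  if (any(evap_mm < 0, na.rm = TRUE)) stop_af("negative evaporation")
  for (y in unique(year)) {
    d <- day[year == y]
    if (length(d) != 365 || !identical(sort(d), 1:365)) {
      stop_af("year %s does not have exactly days 1..365", y)
    }
  }
  df <- data.frame(year = as.integer(year), day = as.integer(day),
                   precip_mm = as.numeric(precip_mm),
                   evap_mm = as.numeric(evap_mm))
  if (!is.null(tmean_c)) df$tmean_c <- as.numeric(tmean_c)
  class(df) <- c("af_climate", "data.frame")
  df
}

#' @export
print.af_climate <- function(x, ...) {
  tot <- annual_totals(x)
  cat(sprintf(
    "<af_climate> %d years x 365 days; annual precip mean %.1f mm (range %.1f-%.1f), %d drought years (< 66 mm)\n",
    length(tot), mean(tot), min(tot), max(tot), sum(tot < 66)
  ))
  invisible(x)
}

#' Annual precipitation totals
#'
#' @param series An `af_climate` series.
#' @return Named numeric vector of annual totals (mm), one per year.
#' @export
annual_totals <- function(series) {
  tot <- tapply(series$precip_mm, series$year, sum)
  stats::setNames(as.vector(tot), names(tot))
}

#' Classify drought years
#'
#' A year is a (climatic) drought iff its total precipitation is strictly
#' below `threshold_mm`.
#'
#' @param series An `af_climate` series.
#' @param threshold_mm Drought threshold (mm/yr, default 66).
#' @return Named logical vector, one element per year.
#' @export
classify_drought_years <- function(series, threshold_mm = 66) {
  tot <- annual_totals(series)
  stats::setNames(as.vector(tot) < threshold_mm, names(tot))
}

#' Linear temperature-to-evaporation transfer
#'
#' Daily evaporation is estimated as `max(0, a * T + b)`; negative predictions
#' clamp to zero. Coefficients default to a transfer fitted for hot desert
#' stations (winter ~2 mm/day, mid-summer ~8 mm/day).
#'
#' @param tmean_c Numeric vector of daily mean temperatures (deg C).
#' @param coeffs Numeric `c(a, b)`.
#' @return Evaporation in mm/day.
#' @export
temp_to_evaporation <- function(tmean_c, coeffs = c(a = 0.35, b = -1.5)) {
  if (any(!is.finite(tmean_c))) stop_af("non-finite temperature")
  pmax(0, coeffs[[1]] * tmean_c + coeffs[[2]])
}

#' Fit the temperature-to-evaporation coefficients
#'
#' Ordinary least squares of paired daily (temperature, evaporation)
#' observations.
#'
#' @param tmean_c,evap_mm Paired observations.
#' @return List with `a`, `b` and `r_squared`.
#' @export
fit_evaporation_coeffs <- function(tmean_c, evap_mm) {
  ok <- is.finite(tmean_c) & is.finite(evap_mm)
  if (sum(ok) < 3) stop_af("need at least 3 paired observations")
  fit <- stats::lm(evap_mm[ok] ~ tmean_c[ok])
  list(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared))
}

#' Fill gaps in a daily precipitation series by inter-station regression
#'
#' Gaps (`NA` in the target's `precip_mm`) are reconstructed with the
#' least-squares linear map from a day-aligned reference station, the standard
#' procedure for extending a short desert rainfall record from a nearby
#' long-running station. Filled values are clamped at zero.
#'
#' @param target Data.frame with `precip_mm` (may contain `NA`).
#' @param reference Data.frame with `precip_mm`, same length, day-aligned.
#' @param min_overlap Minimum overlapping observed days (default 30).
#' @return List: `filled` (target with gaps replaced), `report` with `slope`,
#'   `intercept`, `r_squared`, `deviation_pct` (percent deviation between the
#'   observed and reconstructed mean on the overlap) and `n_overlap`.
#' @export
gap_fill_by_regression <- function(target, reference, min_overlap = 30) {
  if (nrow(target) != nrow(reference)) stop_af("series must be day-aligned (equal length)")
  x <- reference$precip_mm
  y <- target$precip_mm
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_overlap) {
    stop_af("insufficient overlap: %d days with data in both series (need %d)",
            sum(ok), min_overlap)
  }
  fit <- stats::lm(y[ok] ~ x[ok])
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- suppressWarnings(summary(fit)$r.squared) # exact fits are legitimate
  recon <- pmax(0, slope * x[ok] + intercept)
  dev_pct <- if (mean(y[ok]) > 0) 100 * abs(mean(recon) - mean(y[ok])) / mean(y[ok]) else 0
  gaps <- is.na(y) & !is.na(x)
  y[gaps] <- pmax(0, slope * x[gaps] + intercept)
  filled <- target
  filled$precip_mm <- y
  list(
    filled = filled,
    report = list(slope = slope, intercept = intercept, r_squared = r2,
                  deviation_pct = dev_pct, n_overlap = sum(ok))
  )
}

#' Inject a run of consecutive drought years
#'
#' Each year in the drought window is rescaled multiplicatively so its annual
#' total equals a uniform draw in `[0.5, 0.95] * threshold_mm`, preserving the
#' year's intra-season event pattern; all other years are untouched (bitwise).
#'
#' @param series An `af_climate` series.
#' @param start_year First drought year (year id as in `series$year`).
#' @param length_years Number of consecutive drought years (0-5; 0 is a no-op).
#' @param seed Integer seed for the target-total draws.
#' @param threshold_mm Drought threshold (mm, default 66).
#' @return The modified `af_climate` series.
#' @export
inject_drought <- function(series, start_year, length_years, seed = 1,
                           threshold_mm = 66) {
  if (length_years == 0) return(series)
  if (length_years < 0 || length_years > 5) {
    stop_af("length_years must be in 0..5, got %s", length_years)
  }
  years <- sort(unique(series$year))
  window <- start_year + seq_len(length_years) - 1L
  if (!all(window %in% years)) {
    stop_af("drought window [%d, %d] outside series years [%d, %d]",
            min(window), max(window), min(years), max(years))
  }
  targets <- with_seed(seed, stats::runif(length_years, 0.5, 0.95) * threshold_mm)
  for (j in seq_along(window)) {
    sel <- series$year == window[j]
    tot <- sum(series$precip_mm[sel])
    if (tot > 0) {
      series$precip_mm[sel] <- series$precip_mm[sel] * (targets[j] / tot)
    }
  }
  series
}

#' Scale a series toward a wetter climate
#'
#' Multiplies every daily precipitation by `factor`; evaporation is unchanged.
#'
#' @param series An `af_climate` series.
#' @param factor Precipitation multiplier (>= 1; e.g. 1.10 or 1.25).
#' @return The scaled series.
#' @export
scale_wetter <- function(series, factor) {
  if (factor < 1) stop_af("factor must be >= 1, got %g", factor)
  series$precip_mm <- series$precip_mm * factor
  series
}

#' Generate a synthetic desert climate
#'
#' Winter-concentrated rainfall for an arid site: on each wet-season day an
#' event occurs with a Bernoulli probability modulated by a lognormal yearly
#' wetness factor, and event depths are gamma distributed (many small events,
#' rare heavy ones). Defaults are calibrated so that the long-run annual mean
#' is `annual_mean_mm` (87 mm) and a dry year (< 66 mm) occurs with
#' probability ~0.37, i.e. roughly every 2.7 years. Daily temperature follows
#' a seasonal sinusoid and evaporation derives from it through
#' [temp_to_evaporation()].
#'
#' @param seed Integer seed; identical seeds give identical series.
#' @param n_years Number of 365-day years (>= 1).
#' @param annual_mean_mm Target long-run mean annual precipitation (mm).
#' @param wet_season_days Length of the wet season starting at day 1 (days).
#' @param event_mean_mm Mean depth of a rain event (mm).
#' @param event_shape Gamma shape of event depths.
#' @param year_sd_log Standard deviation of the log yearly wetness factor.
#' @param evap_coeffs Temperature-to-evaporation coefficients `c(a, b)`.
#' @return An `af_climate` series with a `tmean_c` column.
#' @export
make_synthetic_climate <- function(seed = 1, n_years = 10, annual_mean_mm = 87,
                                   wet_season_days = 210, event_mean_mm = 5.4,
                                   event_shape = 0.65, year_sd_log = 0.36,
                                   evap_coeffs = c(a = 0.35, b = -1.5)) {
  if (n_years < 1) stop_af("n_years must be >= 1")
  q0 <- annual_mean_mm / (wet_season_days * event_mean_mm)
  with_seed(seed, {
    lam <- stats::rlnorm(n_years, meanlog = -year_sd_log^2 / 2, sdlog = year_sd_log)
    out <- vector("list", n_years)
    doy <- 1:365
    # coldest around mid wet season (day ~105 = mid January), hottest in summer
    t_base <- 19 - 9 * cos(2 * pi * (doy - 105) / 365)
    for (y in seq_len(n_years)) {
      p <- numeric(365)
      q <- min(0.85, q0 * lam[y])
      wet <- stats::runif(wet_season_days) < q
      n_ev <- sum(wet)
      if (n_ev > 0) {
        p[which(wet)] <- stats::rgamma(n_ev, shape = event_shape,
                                       scale = event_mean_mm / event_shape)
      }
      tmean <- t_base + stats::rnorm(365, 0, 1.5)
      out[[y]] <- data.frame(year = y, day = doy, precip_mm = p,
                             tmean_c = tmean)
    }
    df <- do.call(rbind, out)
    climate_series(df$year, df$day, df$precip_mm,
                   temp_to_evaporation(df$tmean_c, evap_coeffs),
                   tmean_c = df$tmean_c)
  })
}

#' Write a climate series as CSV
#'
#' CSV dialect: header `date,precip_mm,evap_mm[,tmean_c]`, ISO-8601 dates,
#' UTF-8. Model years are mapped onto consecutive calendar days from
#' `start_date`, skipping February 29 so that every model year spans exactly
#' 365 calendar rows.
#'
#' @param series An `af_climate` series.
#' @param path Output path.
#' @param start_date First calendar day (default "2000-10-01").
#' @return `path`, invisibly.
#' @export
write_climate_csv <- function(series, path, start_date = "2000-10-01") {
  n <- nrow(series)
  d0 <- as.Date(start_date)
  # enough calendar days to cover n rows after dropping Feb 29
  cal <- seq(d0, by = "day", length.out = n + ceiling(n / 365) + 2)
  cal <- cal[!(format(cal, "%m-%d") == "02-29")][seq_len(n)]
  df <- data.frame(date = format(cal, "%Y-%m-%d"),
                   precip_mm = series$precip_mm, evap_mm = series$evap_mm)
  if (!is.null(series$tmean_c)) df$tmean_c <- series$tmean_c
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a daily climate series from CSV
#'
#' Requires columns `date`, `precip_mm` and at least one of `evap_mm`,
#' `tmean_c` (evaporation is synthesized from temperature when absent).
#' Dates must be consecutive calendar days; February 29 rows are dropped with
#' a warning (a model year is exactly 365 ticks); the remaining days are
#' chunked into consecutive 365-day model years and a trailing partial year is
#' dropped with a warning.
#'
#' @param path CSV path.
#' @param evap_coeffs Coefficients for [temp_to_evaporation()] when only
#'   temperature is present.
#' @return An `af_climate` series.
#' @export
read_climate_csv <- function(path, evap_coeffs = c(a = 0.35, b = -1.5)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!("date" %in% names(df)) || !("precip_mm" %in% names(df))) {
    stop_af("climate CSV must have columns 'date' and 'precip_mm'")
  }
  if (!("evap_mm" %in% names(df)) && !("tmean_c" %in% names(df))) {
    stop_af("climate CSV needs 'evap_mm' or 'tmean_c'")
  }
  neg <- which(df$precip_mm < 0)
  if (length(neg)) stop_af("negative precipitation at row %d", neg[1])
  dates <- as.Date(df$date)
  if (any(is.na(dates))) stop_af("unparseable date at row %d", which(is.na(dates))[1])
  leap <- format(dates, "%m-%d") == "02-29"
  if (any(leap)) {
    warning(sprintf("dropping %d Feb-29 row(s): model years are 365 ticks", sum(leap)))
    df <- df[!leap, , drop = FALSE]
    dates <- dates[!leap]
  }
  # completeness: consecutive days apart from the dropped Feb 29s
  expected <- seq(dates[1], by = "day", length.out = as.integer(dates[length(dates)] - dates[1]) + 1)
  expected <- expected[!(format(expected, "%m-%d") == "02-29")]
  miss <- setdiff(as.character(expected), as.character(dates))
  if (length(miss)) stop_af("missing calendar day %s", miss[1])
  n_full <- nrow(df) %/% 365
  if (n_full < 1) stop_af("fewer than 365 daily rows")
  if (nrow(df) %% 365 != 0) {
    warning(sprintf("dropping trailing partial year (%d rows)", nrow(df) %% 365))
    df <- df[seq_len(n_full * 365), , drop = FALSE]
  }
  evap <- if ("evap_mm" %in% names(df)) {
    df$evap_mm
  } else {
    temp_to_evaporation(df$tmean_c, evap_coeffs)
  }
  climate_series(
    year = rep(seq_len(n_full), each = 365),
    day = rep(1:365, n_full),
    precip_mm = df$precip_mm,
    evap_mm = evap,
    tmean_c = if ("tmean_c" %in% names(df)) df$tmean_c else NULL
  )
}

#' Assemble a decade (or any horizon) by resampling years from a library
#'
#' Samples `n_years` year ids with replacement from an existing series
#' (optionally restricted to non-drought years) and concatenates them into a
#' new series with years renumbered 1..n_years.
#'
#' @param library_series An `af_climate` series to draw from.
#' @param n_years Years in the assembled series.
#' @param seed Integer seed.
#' @param exclude_drought If `TRUE`, only years with >= 66 mm are drawn.
#' @param fixed_years Optional integer vector: positions (1..n_years) whose
#'   source year should be drawn from the non-drought pool regardless.
#' @return An `af_climate` series.
#' @export
sample_years <- function(library_series, n_years, seed = 1,
                         exclude_drought = FALSE, fixed_years = NULL) {
  years <- sort(unique(library_series$year))
  dr <- classify_drought_years(library_series)
  pool <- if (exclude_drought) years[!dr[as.character(years)]] else years
  if (!length(pool)) stop_af("no candidate years in library")
  wet_pool <- years[!dr[as.character(years)]]
  picks <- with_seed(seed, {
    p <- sample(pool, n_years, replace = TRUE)
    if (!is.null(fixed_years) && length(wet_pool)) {
      p[fixed_years] <- sample(wet_pool, length(fixed_years), replace = TRUE)
    }
    p
  })
  rows_by_year <- split(seq_len(nrow(library_series)), library_series$year)
  idx <- unlist(rows_by_year[as.character(picks)], use.names = FALSE)
  df <- data.frame(
    year = rep(seq_len(n_years), each = 365),
    day = library_series$day[idx],
    precip_mm = library_series$precip_mm[idx],
    evap_mm = library_series$evap_mm[idx]
  )
  class(df) <- c("af_climate", "data.frame")
  df
}
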