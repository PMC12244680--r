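# The four climate-stress experiments as replicated Monte-Carlo sweeps:
# runoff-ratio efficiency sweep, consecutive-drought impact, post-drought
# recovery time, and wetter-climate scenarios. Each replicate assembles its
# decade (or 20-year horizon) by resampling years from a shared synthetic
# climate library; replicate seeds derive deterministically from the base
# seed, so every sweep replays bit-for-bit.

.sweep_base <- function(seed, config, library_years) {
  watershed <- make_synthetic_watershed(
    seed = config$watershed_seed, n_rows = config$n_rows, n_cols = config$n_cols,
    relief_m = config$relief_m, channel_slope = config$channel_slope,
    noise_sd = config$noise_sd, cell_size = config$cell_size
  )
  library_climate <- make_synthetic_climate(
    seed = derive_seed(seed, 2), n_years = library_years,
    annual_mean_mm = config$annual_mean_mm, year_sd_log = config$year_sd_log,
    event_mean_mm = config$event_mean_mm, event_shape = config$event_shape,
    wet_season_days = config$wet_season_days, evap_coeffs = config$evap_coeffs
  )
  list(watershed = watershed, library = library_climate)
}

#' Test 1: grapevine yield efficiency across runoff ratios
#'
#' For each runoff ratio, `replicates` independent decades are assembled by
#' resampling years (with replacement) from the synthetic climate library and
#' simulated in full; the decade-mean grape yield efficiency of each run is
#' recorded (26 ratios x 40 replicates = 1,040 random decades by default).
#'
#' @param seed Base seed; replicate seeds derive from (seed, ratio, replicate).
#' @param r_values Runoff ratios to sweep (default 5..30).
#' @param replicates Replicates per ratio (default 40; reduced-replicate runs
#'   are flagged in the metadata).
#' @param years Years per replicate (default 10).
#' @param config Base [sim_config()]; the runoff ratio is overridden per cell.
#' @param library_years Size of the shared synthetic climate library.
#' @param verbose Log per-ratio progress to stderr.
#' @return Data.frame (r, replicate, efficiency, mean_wine_l) with attribute
#'   `metadata`.
#' @export
run_T1_runoff_sweep <- function(seed = 1, r_values = 5:30, replicates = 40,
                                years = 10, config = sim_config(),
                                library_years = 60, verbose = FALSE) {
  base <- .sweep_base(seed, config, library_years)
  out <- vector("list", length(r_values))
  for (ri in seq_along(r_values)) {
    r <- r_values[ri]
    cfg <- config
    cfg$runoff_ratio <- r
    cfg$years <- years
    lu <- assign_land_use(
      base$watershed, runoff_ratio = r, wheat_ratio = cfg$wheat_ratio,
      n_farms = cfg$n_farms, grape_per_farm = cfg$grape_per_farm,
      wheat_per_farm = cfg$wheat_per_farm, mounds = cfg$mounds,
      reserve_sites = cfg$reserve_sites
    )
    eff <- wine <- numeric(replicates)
    for (rep in seq_len(replicates)) {
      s <- derive_seed(seed, ri, rep)
      decade <- sample_years(base$library, years, seed = s)
      run <- run_simulation(cfg, base$watershed, decade, landuse = lu, seed = s)
      eff[rep] <- run_grape_efficiency(run)
      wine[rep] <- mean(run$annual$wine_l)
    }
    if (verbose) message(sprintf("T1: ratio %d done", r))
    out[[ri]] <- data.frame(r = r, replicate = seq_len(replicates),
                            efficiency = eff, mean_wine_l = wine)
  }
  res <- do.call(rbind, out)
  attr(res, "metadata") <- list(
    test = "T1", seed = seed, replicates = replicates,
    reduced_power = replicates < 40, n_runs = nrow(res)
  )
  res
}

#' Summary statistics of a sweep column
#'
#' Mean, SD, normal-approximation 95% CI, min and max.
#'
#' @param x Numeric vector of replicate values.
#' @return Named numeric vector.
#' @export
sweep_summary <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- stats::sd(x)
  c(n = n, mean = m, sd = s,
    ci_lower = m - 1.96 * s / sqrt(n), ci_upper = m + 1.96 * s / sqrt(n),
    min = min(x), max = max(x))
}

.drought_class <- function(len) {
  ifelse(len == 0, "none",
         ifelse(len <= 2, "short", ifelse(len <= 4, "medium", "long")))
}

#' Test 2: impact of consecutive drought years on wine production
#'
#' Decades with 0-5 consecutive injected drought years (each rescaled below
#' the 66 mm threshold, starting at a random feasible position within the
#' decade); each drought length runs `replicates` times. Default class sample
#' sizes are 100 (none), 200 (short, 1-2 yr), 200 (medium, 3-4 yr) and 100
#' (long, 5 yr) - 600 runs in total.
#'
#' @param seed Base seed.
#' @param lengths Drought lengths to test (default 0:5).
#' @param replicates Replicates per drought length.
#' @param years Decade length (default 10).
#' @param config Base [sim_config()].
#' @param library_years Climate library size.
#' @param verbose Log progress.
#' @return Data.frame (drought_length, class, replicate, mean_wine_l) with
#'   attribute `metadata`.
#' @export
run_T2_drought_impact <- function(seed = 1, lengths = 0:5, replicates = 100,
                                  years = 10, config = sim_config(),
                                  library_years = 60, verbose = FALSE) {
  base <- .sweep_base(seed, config, library_years)
  cfg <- config
  cfg$years <- years
  lu <- assign_land_use(
    base$watershed, runoff_ratio = cfg$runoff_ratio, wheat_ratio = cfg$wheat_ratio,
    n_farms = cfg$n_farms, grape_per_farm = cfg$grape_per_farm,
    wheat_per_farm = cfg$wheat_per_farm, mounds = cfg$mounds,
    reserve_sites = cfg$reserve_sites
  )
  out <- vector("list", length(lengths))
  for (li in seq_along(lengths)) {
    len <- lengths[li]
    wine <- numeric(replicates)
    for (rep in seq_len(replicates)) {
      # decades are drawn per replicate index, shared across drought lengths
      # (common random numbers): the class contrast is paired, which leaves
      # the reduction estimates unbiased but much tighter
      s_dec <- derive_seed(seed, 100, rep)
      s <- derive_seed(seed, 100 + len, rep)
      decade <- sample_years(base$library, years, seed = s_dec)
      if (len > 0) {
        start <- with_seed(derive_seed(s, 7), sample.int(years - len + 1, 1))
        decade <- inject_drought(decade, start, len, seed = derive_seed(s, 8))
      }
      run <- run_simulation(cfg, base$watershed, decade, landuse = lu, seed = s)
      wine[rep] <- mean(run$annual$wine_l)
    }
    if (verbose) message(sprintf("T2: drought length %d done", len))
    out[[li]] <- data.frame(drought_length = len,
                            class = .drought_class(len),
                            replicate = seq_len(replicates),
                            mean_wine_l = wine)
  }
  res <- do.call(rbind, out)
  attr(res, "metadata") <- list(
    test = "T2", seed = seed, replicates = replicates,
    reduced_power = replicates < 100, n_runs = nrow(res)
  )
  res
}

#' Percent production reduction per drought class
#'
#' `reduction_pct = 100 * (1 - mean_class / mean_none)`.
#'
#' @param t2 Result of [run_T2_drought_impact()].
#' @return Data.frame per class with [sweep_summary()] columns and
#'   `reduction_pct`.
#' @export
drought_reductions <- function(t2) {
  classes <- intersect(c("none", "short", "medium", "long"), unique(t2$class))
  stats <- t(vapply(classes, function(cl) {
    sweep_summary(t2$mean_wine_l[t2$class == cl])
  }, numeric(7)))
  base_mean <- if ("none" %in% classes) stats["none", "mean"] else NA_real_
  data.frame(class = classes, stats,
             reduction_pct = 100 * (1 - stats[, "mean"] / base_mean),
             row.names = NULL)
}

#' Test 3: post-drought recovery time
#'
#' 20-year horizons: a 5-year non-drought baseline window, then an injected
#' drought of the given length, then resampled years. Recovery is the first
#' post-drought year whose wine production strictly exceeds the baseline-mean
#' production of years 1-5 (`NA` when never within the horizon); replicates
#' with no recovery within a decade of the drought's end are flagged
#' censored.
#'
#' @param seed Base seed.
#' @param lengths Drought lengths (default 2:5).
#' @param replicates Replicates per length (default 100).
#' @param years Horizon (default 20).
#' @param config Base [sim_config()].
#' @param library_years Climate library size.
#' @param verbose Log progress.
#' @return Data.frame (drought_length, class, replicate, baseline_wine_l,
#'   recovery_years, censored) with attribute `metadata`.
#' @export
run_T3_recovery <- function(seed = 1, lengths = 2:5, replicates = 100,
                            years = 20, config = sim_config(),
                            library_years = 60, verbose = FALSE) {
  base <- .sweep_base(seed, config, library_years)
  cfg <- config
  cfg$years <- years
  lu <- assign_land_use(
    base$watershed, runoff_ratio = cfg$runoff_ratio, wheat_ratio = cfg$wheat_ratio,
    n_farms = cfg$n_farms, grape_per_farm = cfg$grape_per_farm,
    wheat_per_farm = cfg$wheat_per_farm, mounds = cfg$mounds,
    reserve_sites = cfg$reserve_sites
  )
  out <- vector("list", length(lengths))
  for (li in seq_along(lengths)) {
    len <- lengths[li]
    baseline <- rec <- numeric(replicates)
    cens <- logical(replicates)
    for (rep in seq_len(replicates)) {
      s <- derive_seed(seed, 200 + len, rep)
      horizon <- sample_years(base$library, years, seed = s, fixed_years = 1:5)
      horizon <- inject_drought(horizon, 6, len, seed = derive_seed(s, 8))
      run <- run_simulation(cfg, base$watershed, horizon, landuse = lu, seed = s)
      wine <- run$annual$wine_l
      baseline[rep] <- mean(wine[1:5])
      post <- wine[(5 + len + 1):years]
      hit <- which(post > baseline[rep])
      rec[rep] <- if (length(hit)) hit[1] else NA_real_
      cens[rep] <- is.na(rec[rep]) | (!is.na(rec[rep]) && rec[rep] > 10)
    }
    if (verbose) message(sprintf("T3: drought length %d done", len))
    out[[li]] <- data.frame(drought_length = len, class = .drought_class(len),
                            replicate = seq_len(replicates),
                            baseline_wine_l = baseline,
                            recovery_years = rec, censored = cens)
  }
  res <- do.call(rbind, out)
  attr(res, "metadata") <- list(
    test = "T3", seed = seed, replicates = replicates,
    reduced_power = replicates < 100, n_runs = nrow(res)
  )
  res
}

#' Recovery-time summary per drought class
#'
#' The class mean is computed over recovered replicates (those with a
#' recovery year inside the horizon); the fraction failing to recover within
#' a decade of the drought's end is reported separately.
#'
#' @param t3 Result of [run_T3_recovery()].
#' @return Data.frame per class.
#' @export
recovery_summary <- function(t3) {
  classes <- intersect(c("short", "medium", "long"), unique(t3$class))
  rows <- lapply(classes, function(cl) {
    x <- t3[t3$class == cl, ]
    rec <- x$recovery_years[!is.na(x$recovery_years)]
    data.frame(
      class = cl, n = nrow(x), n_recovered = length(rec),
      mean = mean(rec), sd = stats::sd(rec), min = min(rec), max = max(rec),
      failed_decade_frac = mean(x$censored)
    )
  })
  do.call(rbind, rows)
}

#' Test 4: wetter-climate scenarios across the runoff-ratio sweep
#'
#' Repeats the Test-1 design under precipitation factors (1.0, 1.10, 1.25)
#' with identical replicate seeds and decades, scaling each decade's daily
#' precipitation before simulation.
#'
#' @param seed Base seed (use the same value as the Test-1 sweep to share
#'   decades with it).
#' @param factors Precipitation multipliers.
#' @param r_values,replicates,years,config,library_years,verbose As in
#'   [run_T1_runoff_sweep()].
#' @return Data.frame (factor, r, replicate, efficiency) with attribute
#'   `metadata`.
#' @export
run_T4_wetter <- function(seed = 1, factors = c(1, 1.1, 1.25),
                          r_values = 5:30, replicates = 40, years = 10,
                          config = sim_config(), library_years = 60,
                          verbose = FALSE) {
  base <- .sweep_base(seed, config, library_years)
  out <- list()
  for (ri in seq_along(r_values)) {
    r <- r_values[ri]
    cfg <- config
    cfg$runoff_ratio <- r
    cfg$years <- years
    lu <- assign_land_use(
      base$watershed, runoff_ratio = r, wheat_ratio = cfg$wheat_ratio,
      n_farms = cfg$n_farms, grape_per_farm = cfg$grape_per_farm,
      wheat_per_farm = cfg$wheat_per_farm, mounds = cfg$mounds,
      reserve_sites = cfg$reserve_sites
    )
    for (rep in seq_len(replicates)) {
      s <- derive_seed(seed, ri, rep)
      decade <- sample_years(base$library, years, seed = s)
      for (fa in factors) {
        dec <- if (fa == 1) decade else scale_wetter(decade, fa)
        run <- run_simulation(cfg, base$watershed, dec, landuse = lu, seed = s)
        out[[length(out) + 1L]] <- data.frame(
          factor = fa, r = r, replicate = rep,
          efficiency = run_grape_efficiency(run)
        )
      }
    }
    if (verbose) message(sprintf("T4: ratio %d done", r))
  }
  res <- do.call(rbind, out)
  attr(res, "metadata") <- list(
    test = "T4", seed = seed, replicates = replicates,
    reduced_power = replicates < 40, n_runs = nrow(res)
  )
  res
}

#' Efficiency gains of wetter climates
#'
#' `gain_pct = 100 * (mean_group / mean_baseline - 1)` per precipitation
#' factor.
#'
#' @param t4 Result of [run_T4_wetter()].
#' @return Data.frame per climate group.
#' @export
wetter_gains <- function(t4) {
  factors <- sort(unique(t4$factor))
  stats <- t(vapply(factors, function(fa) {
    sweep_summary(t4$efficiency[t4$factor == fa])
  }, numeric(7)))
  base_mean <- stats[which(factors == min(factors)), "mean"]
  data.frame(factor = factors, stats,
             gain_pct = 100 * (stats[, "mean"] / base_mean - 1),
             row.names = NULL)
}
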