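# Simulation engine: daily tick loop (climate -> hydrology), annual close
# (yields -> economy -> decisions), seeded reproducibility and structured
# long-format outputs.

.config_fields <- c(
  "years", "n_farms", "grape_per_farm", "wheat_per_farm",
  "runoff_ratio", "wheat_ratio", "mounds", "reserve_sites",
  "initial_storage_kg", "price_ratio", "initial_vine_age", "vine_death_years",
  "expansion_reserve_kg", "storage_cap_kg",
  "memory_window", "f_max", "expansion_step",
  "capacity_mm", "infiltration_mm",
  "cn_table", "lambda", "mound_multiplier", "calibration_factor",
  "yield", "labor", "thresholds",
  "n_rows", "n_cols", "relief_m", "channel_slope", "noise_sd", "cell_size",
  "watershed_seed",
  "annual_mean_mm", "year_sd_log", "event_mean_mm", "event_shape",
  "wet_season_days", "evap_coeffs"
)

#' Build a validated simulation configuration
#'
#' Collects every model parameter with its default. Unknown keys are
#' rejected. Defaults encode the study conditions: 30-m cells, CN 92/85/77,
#' calibration factor 1.567, mound multiplier 1.3, 0.09-ha terraces,
#' 87 mm/yr climate with ~0.37 drought probability, labor costs from the
#' wheat-equivalent table, and the calibrated yield curves.
#'
#' @param ... Named overrides of any configuration field.
#' @return List of class `af_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    years = 10, n_farms = 10, grape_per_farm = 2, wheat_per_farm = 2,
    runoff_ratio = 20, wheat_ratio = 5, mounds = TRUE, reserve_sites = 15,
    initial_storage_kg = 350, price_ratio = 0.5, initial_vine_age = 5,
    vine_death_years = 3, expansion_reserve_kg = 170, storage_cap_kg = 1000,
    memory_window = 5, f_max = 2, expansion_step = 1,
    capacity_mm = 150, infiltration_mm = c(R = 6, S = 8, X = 10),
    cn_table = c(R = 92, S = 85, X = 77), lambda = 0.2,
    mound_multiplier = 1.3, calibration_factor = 1.567,
    yield = yield_params(), labor = labor_table(),
    thresholds = outcome_thresholds(),
    n_rows = 60, n_cols = 50, relief_m = 120, channel_slope = 0.01,
    noise_sd = 0.1, cell_size = 30, watershed_seed = 42,
    annual_mean_mm = 87, year_sd_log = 0.36, event_mean_mm = 5.4,
    event_shape = 0.65, wet_season_days = 210,
    evap_coeffs = c(a = 0.35, b = -1.5)
  )
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == ""))) {
    stop_af("all configuration overrides must be named")
  }
  bad <- setdiff(names(over), .config_fields)
  if (length(bad)) stop_af("unknown configuration keys: %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$years < 1) stop_af("years must be >= 1")
  structure(cfg, class = "af_config")
}

#' Read / write a configuration as YAML
#'
#' Scalar and vector fields round-trip through a structured-text file;
#' nested parameter blocks (`yield`, `labor`) are stored as plain maps.
#'
#' @param path YAML file path.
#' @param config An [sim_config()] object (write).
#' @return `read_config`: an `af_config`; `write_config`: `path`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$yield)) args$yield <- do.call(yield_params, raw$yield)
  if (!is.null(raw$labor)) args$labor <- do.call(labor_table, raw$labor)
  for (nm in c("infiltration_mm", "cn_table", "evap_coeffs")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- unlist(raw[[nm]])
  }
  do.call(sim_config, args)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  out$yield <- unclass(out$yield)
  out$labor <- unclass(out$labor)
  out$thresholds <- NULL # fixed by outcome_thresholds()
  for (nm in c("infiltration_mm", "cn_table", "evap_coeffs")) {
    out[[nm]] <- as.list(out[[nm]]) # keep names: yaml drops them on vectors
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run a full simulation
#'
#' Executes `config$years` years: 365 daily hydrology ticks per year, then
#' the annual close — water-limited yields, wheat-equivalent settlement,
#' loss-averse farm decisions (reactivation, expansion, wheat reassessment) —
#' and seasonal accumulator resets. Fully deterministic for a fixed seed.
#'
#' @param config An [sim_config()].
#' @param watershed Optional `af_watershed`; generated synthetically from the
#'   seed when `NULL`.
#' @param climate Optional `af_climate` with at least `config$years` years;
#'   generated synthetically when `NULL`.
#' @param landuse Optional precomputed [assign_land_use()] result for
#'   `watershed` (must match the config's ratios); assigned here when `NULL`.
#' @param seed Integer seed for all randomness.
#' @return List of class `af_run`: `terraces` (per year x terrace),
#'   `farms` (per year x farm), `annual` (basin aggregates and ledgers),
#'   `config`, `seed`.
#' @export
run_simulation <- function(config = sim_config(), watershed = NULL,
                           climate = NULL, landuse = NULL, seed = 1) {
  cfg <- config
  if (is.null(watershed)) {
    # the basin is study geography, not a random effect: it comes from its own
    # configured seed so that run seeds vary climate and replication only
    watershed <- make_synthetic_watershed(
      seed = cfg$watershed_seed, n_rows = cfg$n_rows, n_cols = cfg$n_cols,
      relief_m = cfg$relief_m, channel_slope = cfg$channel_slope,
      noise_sd = cfg$noise_sd, cell_size = cfg$cell_size
    )
  }
  if (is.null(climate)) {
    climate <- make_synthetic_climate(
      seed = derive_seed(seed, 2), n_years = cfg$years,
      annual_mean_mm = cfg$annual_mean_mm, year_sd_log = cfg$year_sd_log,
      event_mean_mm = cfg$event_mean_mm, event_shape = cfg$event_shape,
      wet_season_days = cfg$wet_season_days, evap_coeffs = cfg$evap_coeffs
    )
  }
  years_avail <- length(unique(climate$year))
  if (years_avail < cfg$years) {
    stop_af("climate provides %d years, %d requested", years_avail, cfg$years)
  }
  if (is.null(landuse)) {
    landuse <- assign_land_use(
      watershed, runoff_ratio = cfg$runoff_ratio, wheat_ratio = cfg$wheat_ratio,
      n_farms = cfg$n_farms, grape_per_farm = cfg$grape_per_farm,
      wheat_per_farm = cfg$wheat_per_farm, mounds = cfg$mounds,
      reserve_sites = cfg$reserve_sites
    )
  }
  params <- cn_params(cn_table = cfg$cn_table, lambda = cfg$lambda,
                      mound_multiplier = cfg$mound_multiplier,
                      calibration_factor = cfg$calibration_factor)
  basin <- compile_basin(watershed, landuse, params,
                         capacity_mm = cfg$capacity_mm,
                         infiltration_mm = cfg$infiltration_mm)
  yp <- cfg$yield
  labor <- cfg$labor
  cell_area <- (cfg$cell_size^2) / 1e4

  # mutable terrace-level state
  crop <- basin$crop
  farm <- basin$farm
  nt <- basin$n_terraces
  active <- rep(TRUE, nt)
  vine_age <- ifelse(crop == "grape", cfg$initial_vine_age, NA_integer_)
  inactive_years <- integer(nt)
  infra_cost <- vapply(seq_len(nt), function(i) {
    .construction_cost(crop[i], length(landuse$catchments[[i]]), labor, cell_area)
  }, numeric(1))
  slots <- landuse$slots
  slot_catch <- landuse$slot_catchments

  storage <- rep(cfg$initial_storage_kg, cfg$n_farms)
  mem_grape <- lapply(seq_len(cfg$n_farms), function(i) new_yield_memory(cfg$memory_window))
  mem_wheat <- lapply(seq_len(cfg$n_farms), function(i) new_yield_memory(cfg$memory_window))
  policy <- decision_policy(f_max = cfg$f_max, expansion_step = cfg$expansion_step)

  state <- water_state(basin)
  p_by_year <- split(climate$precip_mm, climate$year)
  e_by_year <- split(climate$evap_mm, climate$year)
  year_ids <- sort(unique(climate$year))[seq_len(cfg$years)]

  terr_rows <- vector("list", cfg$years)
  farm_rows <- vector("list", cfg$years)
  annual_rows <- vector("list", cfg$years)

  for (y in seq_len(cfg$years)) {
    res <- .run_water_year(basin, state,
                           p_by_year[[as.character(year_ids[y])]],
                           e_by_year[[as.character(year_ids[y])]])
    state <- res$state
    saw <- seasonal_available_water(state)
    w <- saw$available_mm
    state <- saw$state

    mature <- crop == "grape" & !is.na(vine_age) & vine_age >= 4
    yield <- numeric(basin$n_terraces)
    g_act <- which(active & mature)
    yield[g_act] <- grape_yield(w[g_act], yp)
    wh_act <- which(active & crop == "wheat")
    yield[wh_act] <- wheat_yield(w[wh_act], yp)
    eff <- rep(NA_real_, basin$n_terraces)
    eff[crop == "grape"] <- yield_efficiency(yield[crop == "grape"], yp)

    cc <- .costs_core(crop, active, vine_age, infra_cost, labor, yp$fallow_mode)
    cost_total <- cc$maintenance + cc$seasonal
    income_kg <- cost_paid <- numeric(cfg$n_farms)
    storage_in <- storage
    spoiled <- 0
    deact_all <- logical(basin$n_terraces)
    for (f in seq_len(cfg$n_farms)) {
      mine <- which(farm == f)
      inc <- sum(yield[mine][crop[mine] == "wheat"]) +
        grape_income_wheat_equiv(sum(yield[mine][crop[mine] == "grape"]),
                                 cfg$price_ratio)
      st <- .settle_core(storage[f], inc, crop[mine], active[mine],
                         vine_age[mine], cost_total[mine])
      income_kg[f] <- inc
      cost_paid[f] <- storage[f] + inc - st$storage_kg
      # granary limit: surplus beyond the storage capacity spoils
      spoiled <- spoiled + max(0, st$storage_kg - cfg$storage_cap_kg)
      storage[f] <- min(st$storage_kg, cfg$storage_cap_kg)
      deact_all[mine[st$deactivate]] <- TRUE
    }

    # record season before state transitions
    terr_rows[[y]] <- list(
      year = rep(y, basin$n_terraces), terrace = seq_len(basin$n_terraces),
      farm = farm, crop = crop, active = active, mature = mature,
      water_mm = w, yield_kg = yield, efficiency = eff
    )

    # age / deactivate / vine death
    vine_age[active & crop == "grape"] <- vine_age[active & crop == "grape"] + 1L
    active[deact_all] <- FALSE
    inactive_years[active] <- 0L
    inactive_years[!active] <- inactive_years[!active] + 1L
    dead <- !active & crop == "grape" & inactive_years >= cfg$vine_death_years &
      !is.na(vine_age) & vine_age > 0
    vine_age[dead] <- 0L

    outcome_g <- outcome_w <- character(cfg$n_farms)
    action <- character(cfg$n_farms)
    post_pay <- 0 # reactivation / expansion / conversion payments this year
    for (f in seq_len(cfg$n_farms)) {
      mine <- which(farm == f)
      # reactivation: wheat first, then vineyards oldest-first
      inact <- mine[!active[mine]]
      if (length(inact)) {
        pri <- inact[order(crop[inact] != "wheat",
                           -ifelse(is.na(vine_age[inact]), 0, vine_age[inact]))]
        for (i in pri) {
          seasonal <- if (crop[i] == "grape") {
            if (!is.na(vine_age[i]) && vine_age[i] > 3) labor$vine_mature_upkeep else labor$vine_young_upkeep
          } else {
            0.5 * (labor$wheat_season + labor$wheat_seed)
          }
          dead_i <- crop[i] == "grape" && (is.na(vine_age[i]) || vine_age[i] == 0)
          fee <- (1 + labor$reactivation_surcharge) *
            (seasonal + if (dead_i) labor$vine_establish else 0)
          if (storage[f] >= fee) {
            storage[f] <- storage[f] - fee
            post_pay <- post_pay + fee
            active[i] <- TRUE
            inactive_years[i] <- 0L
            if (dead_i) vine_age[i] <- 1L
          }
        }
      }

      # subsistence floor: a household always musters the labor to keep one
      # wheat field cropped; without it a fully-deactivated farm would have
      # zero income forever (storage is a surplus ledger, never a debt)
      if (!any(active[mine])) {
        wf <- mine[crop[mine] == "wheat"]
        if (length(wf)) {
          i <- wf[1]
          fee <- (1 + labor$reactivation_surcharge) *
            0.5 * (labor$wheat_season + labor$wheat_seed)
          pay <- min(storage[f], fee)
          storage[f] <- storage[f] - pay
          post_pay <- post_pay + pay
          active[i] <- TRUE
          inactive_years[i] <- 0L
        }
      }

      gm <- mine[crop[mine] == "grape" & active[mine] &
                   !is.na(vine_age[mine]) & vine_age[mine] > 3]
      wm <- mine[crop[mine] == "wheat" & active[mine]]
      mg <- if (length(gm)) mean(yield[gm]) else 0
      mw <- if (length(wm)) mean(yield[wm]) else 0
      outcome_g[f] <- classify_outcome("grape", mg, cfg$thresholds)
      outcome_w[f] <- classify_outcome("wheat", mw, cfg$thresholds)
      mem_grape[[f]] <- update_memory(mem_grape[[f]], outcome_g[f])
      mem_wheat[[f]] <- update_memory(mem_wheat[[f]], outcome_w[f])

      exp_cost <- labor$vine_establish +
        .construction_cost("grape", cfg$runoff_ratio, labor, cell_area)
      # expansion must leave an operating reserve behind
      act <- decide(outcome_g[f], mem_grape[[f]],
                    storage[f] - cfg$expansion_reserve_kg, exp_cost, policy)
      if (act == "expand_vineyard") {
        if (length(slots)) {
          sl <- slots[[1]]
          cells <- slot_catch[[1]]
          slots <- slots[-1]
          slot_catch <- slot_catch[-1]
          storage[f] <- storage[f] - exp_cost
          post_pay <- post_pay + exp_cost
          basin <- .basin_add_terrace(basin, watershed, sl$cell, cells,
                                      "grape", f, cfg$mounds)
          crop <- c(crop, "grape")
          farm <- c(farm, f)
          active <- c(active, TRUE)
          vine_age <- c(vine_age, 1L)
          inactive_years <- c(inactive_years, 0L)
          infra_cost <- c(infra_cost,
                          .construction_cost("grape", length(cells), labor, cell_area))
          state$column <- c(state$column, 0)
          state$accum <- c(state$accum, 0)
          w <- c(w, NA_real_)
          yield <- c(yield, 0)
          eff <- c(eff, NA_real_)
        } else {
          act <- "hold" # no feasible site left
        }
      } else if (act == "reassess_wheat") {
        n_wheat <- sum(crop[mine] == "wheat")
        n_grape <- sum(crop[mine] == "grape")
        if (n_wheat < n_grape && storage[f] >= labor$wheat_field_create) {
          cand <- mine[crop[mine] == "grape" & active[mine]]
          if (length(cand)) {
            worst <- cand[which.min(yield[cand])]
            crop[worst] <- "wheat"
            vine_age[worst] <- NA_integer_
            storage[f] <- storage[f] - labor$wheat_field_create
            post_pay <- post_pay + labor$wheat_field_create
          }
        }
      }
      action[f] <- act
    }

    farm_rows[[y]] <- list(
      year = rep(y, cfg$n_farms), farm = seq_len(cfg$n_farms), income_kg = income_kg,
      cost_paid_kg = cost_paid, storage_kg = storage,
      storage_in_kg = storage_in,
      outcome_grape = outcome_g, outcome_wheat = outcome_w, action = action,
      consec_failures = vapply(mem_grape, function(m) m$consec_failures, integer(1))
    )

    led <- res$ledger
    tr <- terr_rows[[y]]
    tr_grape <- tr$crop == "grape"
    g_eff <- tr$efficiency[tr_grape & tr$active & tr$mature]
    annual_rows[[y]] <- list(
      year = y,
      precip_mm = sum(p_by_year[[as.character(year_ids[y])]]),
      grape_kg = sum(tr$yield_kg[tr_grape]),
      wheat_kg = sum(tr$yield_kg[!tr_grape]),
      wine_l = wine_volume(sum(tr$yield_kg[tr_grape]), yp$wine_l_per_kg),
      mean_efficiency = if (length(g_eff)) mean(g_eff) else NA_real_,
      n_active_grape = sum(tr$active & tr_grape),
      n_active_wheat = sum(tr$active & !tr_grape),
      water_inflow_mm = led[["inflow"]],
      water_evaporation_mm = led[["evaporation"]],
      water_infiltration_mm = led[["infiltration"]],
      water_outlet_loss_mm = led[["outlet_loss"]],
      water_delta_storage_mm = led[["delta_storage"]],
      wheat_spoiled_kg = spoiled,
      wheat_balance_error_kg = sum(storage_in) + sum(income_kg) -
        sum(cost_paid) - spoiled - post_pay - sum(storage)
    )
  }

  bind_lists <- function(rows) {
    fields <- names(rows[[1]])
    out <- lapply(fields, function(f) unlist(lapply(rows, `[[`, f), use.names = FALSE))
    names(out) <- fields
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  terraces <- bind_lists(terr_rows)
  farms <- bind_lists(farm_rows)
  annual <- bind_lists(annual_rows)
  structure(
    list(terraces = terraces, farms = farms, annual = annual,
         config = cfg, seed = seed, n_terraces_final = basin$n_terraces),
    class = "af_run"
  )
}

#' @export
print.af_run <- function(x, ...) {
  cat(sprintf(
    "<af_run> %d years, %d farms, %d terraces; mean wine %.0f L/yr, mean grape efficiency %.3f\n",
    x$config$years, x$config$n_farms, x$n_terraces_final,
    mean(x$annual$wine_l), mean(x$annual$mean_efficiency, na.rm = TRUE)
  ))
  invisible(x)
}

#' Annual wine production series
#'
#' @param run An `af_run` from [run_simulation()].
#' @return Numeric vector, liters of wine per simulated year.
#' @export
annual_wine_production <- function(run) {
  stats::setNames(run$annual$wine_l, run$annual$year)
}

#' Decade-mean grape yield efficiency of a run
#'
#' Mean efficiency over all active, bearing (age >= 4) grapevine
#' terrace-seasons of the run.
#'
#' @param run An `af_run`.
#' @return A single efficiency in `[0, 1]` (0 when no bearing terraces).
#' @export
run_grape_efficiency <- function(run) {
  tr <- run$terraces
  e <- tr$efficiency[tr$crop == "grape" & tr$active & tr$mature]
  if (!length(e)) return(0)
  mean(e)
}
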