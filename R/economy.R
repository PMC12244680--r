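# Wheat-equivalent labor accounting per farm: construction and seasonal
# activity costs, 10% annual infrastructure maintenance, the storage ledger,
# and affordability checks that drive field deactivation.

#' Labor cost table (kg of wheat per 0.1-ha activity unit)
#'
#' Costs are denominated in kg of wheat at 0.9 kg per man-day (90 kg per 100
#' man-days). Wherever the source gives a range, the midpoint is used:
#' runoff-field clearing 22.5 (18-27), vineyard establishment 33.3
#' (25.0-41.6), young-vine upkeep 10.7/yr (9.2-12.2), mature upkeep including
#' harvest 14.4 (12.8-16).
#'
#' @param ... Named overrides of individual entries.
#' @return List of class `af_labor`.
#' @export
labor_table <- function(...) {
  tab <- list(
    terrace_build = 90, wheat_field_create = 3.6, runoff_clear = 22.5,
    wheat_season = 7.2, wheat_seed = 14.8,
    vine_establish = 33.3, vine_young_upkeep = 10.7, vine_mature_upkeep = 14.4,
    wheat_kg_per_manday = 0.9, maintenance_rate = 0.10,
    reactivation_surcharge = 0.25
  )
  over <- list(...)
  bad <- setdiff(names(over), names(tab))
  if (length(bad)) stop_af("unknown labor entries: %s", paste(bad, collapse = ", "))
  tab[names(over)] <- over
  if (any(unlist(tab) < 0)) stop_af("labor costs must be >= 0")
  structure(tab, class = "af_labor")
}

# construction (infrastructure) cost of a new asset; clearing is charged per
# catchment cell scaled by cell area (0.09 ha per 0.1-ha table unit)
.construction_cost <- function(crop, n_catchment, labor,
                               cell_area_ha = 0.09) {
  clear <- labor$runoff_clear * n_catchment * (cell_area_ha / 0.1)
  if (crop == "grape") {
    labor$terrace_build + clear
  } else {
    labor$wheat_field_create + clear
  }
}

#' Itemized annual cost of a farm's assets
#'
#' Each active asset incurs its age-appropriate seasonal cost plus 10% of its
#' recorded infrastructure construction cost as forced maintenance. Wheat
#' fields in the default half-annual fallow pattern incur half the seasonal
#' work and seed cost every year (in `alternate` mode, full cost in cropped
#' years and half in fallow years). Inactive assets cost nothing.
#'
#' @param assets Data.frame with columns `crop` ("grape"/"wheat"), `active`
#'   (logical), `vine_age` (years; grapes), `infra_cost` (kg wheat),
#'   optionally `fallow_phase` (logical).
#' @param labor An [labor_table()].
#' @param fallow_mode `"half_annual"` or `"alternate"`.
#' @return Data.frame with per-asset `maintenance`, `seasonal`, `total`.
#' @export
annual_cost <- function(assets, labor = labor_table(),
                        fallow_mode = "half_annual") {
  cc <- .costs_core(assets$crop, assets$active, assets$vine_age,
                    assets$infra_cost, labor, fallow_mode,
                    assets$fallow_phase)
  data.frame(maintenance = cc$maintenance, seasonal = cc$seasonal,
             total = cc$maintenance + cc$seasonal)
}

# vectorized cost kernel shared with the engine
.costs_core <- function(crop, active, vine_age, infra_cost, labor,
                        fallow_mode = "half_annual", fallow_phase = NULL) {
  n <- length(crop)
  if (n == 0) return(list(maintenance = numeric(0), seasonal = numeric(0)))
  maintenance <- ifelse(active, labor$maintenance_rate * infra_cost, 0)
  wheat_full <- labor$wheat_season + labor$wheat_seed
  is_grape <- crop == "grape"
  seasonal <- numeric(n)
  seasonal[is_grape] <- ifelse(!is.na(vine_age[is_grape]) & vine_age[is_grape] <= 3,
                               labor$vine_young_upkeep, labor$vine_mature_upkeep)
  if (fallow_mode == "half_annual") {
    seasonal[!is_grape] <- 0.5 * wheat_full
  } else {
    fp <- if (is.null(fallow_phase)) rep(FALSE, n) else fallow_phase
    seasonal[!is_grape] <- ifelse(fp[!is_grape], 0.5 * wheat_full, wheat_full)
  }
  seasonal[!active] <- 0
  list(maintenance = maintenance, seasonal = seasonal)
}

#' Settle a farm's season: income in, costs paid, unaffordable assets flagged
#'
#' Income is credited first; asset costs are then paid in priority order —
#' wheat fields first (subsistence), then vineyards oldest-first — and any
#' asset whose cost cannot be covered is flagged for deactivation next season
#' (its cost goes unpaid). Storage never goes negative: shortfalls cause
#' deactivation, not debt.
#'
#' @param storage_kg Current wheat storage (kg, >= 0).
#' @param income_kg Season income in wheat equivalents (kg, >= 0).
#' @param assets Asset data.frame (see [annual_cost()]).
#' @param costs Per-asset cost data.frame from [annual_cost()].
#' @return List: `storage_kg`, `paid` (logical per asset), `deactivate`
#'   (logical per asset: active assets that could not be paid).
#' @export
settle_season <- function(storage_kg, income_kg, assets, costs) {
  if (storage_kg < 0 || income_kg < 0) stop_af("storage and income must be >= 0")
  .settle_core(storage_kg, income_kg, assets$crop, assets$active,
               assets$vine_age, costs$total)
}

# sequential priority payment kernel shared with the engine:
# wheat first (subsistence), then vineyards oldest-first
.settle_core <- function(storage_kg, income_kg, crop, active, vine_age,
                         cost_total) {
  storage <- storage_kg + income_kg
  n <- length(crop)
  paid <- logical(n)
  deact <- logical(n)
  if (n > 0) {
    age <- ifelse(is.na(vine_age), 0, vine_age)
    pri <- order(crop != "wheat", ifelse(crop == "grape", -age, 0))
    for (i in pri) {
      if (!active[i]) next
      cost <- cost_total[i]
      if (cost <= storage + 1e-12) {
        storage <- storage - cost
        paid[i] <- TRUE
      } else {
        deact[i] <- TRUE
      }
    }
  }
  list(storage_kg = storage, paid = paid, deactivate = deact)
}

#' Convert grape yield to wheat-equivalent income
#'
#' The exchange rate of the cash crop is the largest free economic parameter;
#' with `price_ratio = 0` vineyards are pure cost centers and farms survive
#' on wheat alone (stress-test mode).
#'
#' @param kg_grapes Grape yield (kg).
#' @param price_ratio kg of wheat per kg of grapes (default 0.5).
#' @return Income in kg wheat equivalents.
#' @export
grape_income_wheat_equiv <- function(kg_grapes, price_ratio = 0.5) {
  if (any(kg_grapes < 0) || price_ratio < 0) stop_af("negative grapes or price")
  price_ratio * kg_grapes
}
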