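# Daily water physics: SCS Curve-Number runoff, catchment enhancement
# (mound clearing, basin calibration factor), terrace water columns with
# evaporation/infiltration, and downslope redistribution of excess water.

#' SCS Curve-Number parameters
#'
#' @param cn_table Named integer vector of curve numbers per soil class
#'   (defaults R 92, S 85, X 77).
#' @param lambda Initial-abstraction ratio (classic 0.2).
#' @param mound_multiplier Runoff multiplier for cleared-with-mounds
#'   catchment cells (default 1.3).
#' @param calibration_factor Basin-wide runoff calibration factor applied to
#'   every cell's SCS runoff (default 1.567).
#' @return List of class `af_cn_params`.
#' @export
cn_params <- function(cn_table = c(R = 92, S = 85, X = 77), lambda = 0.2,
                      mound_multiplier = 1.3, calibration_factor = 1.567) {
  if (any(cn_table <= 0 | cn_table > 100)) stop_af("curve numbers must be in (0, 100]")
  if (lambda <= 0 || lambda > 0.5) stop_af("lambda must be in (0, 0.5]")
  if (mound_multiplier < 1) stop_af("mound_multiplier must be >= 1")
  if (calibration_factor <= 0) stop_af("calibration_factor must be > 0")
  structure(list(cn_table = cn_table, lambda = lambda,
                 mound_multiplier = mound_multiplier,
                 calibration_factor = calibration_factor),
            class = "af_cn_params")
}

#' SCS Curve-Number daily runoff
#'
#' Potential maximum retention `S = 25400 / CN - 254` (mm), initial
#' abstraction `Ia = lambda * S`; runoff is 0 when `p <= Ia`, otherwise
#' `(p - Ia)^2 / (p - Ia + S)`. Always `0 <= q <= p`.
#'
#' @param p Daily precipitation (mm, >= 0); vectorized.
#' @param cn Curve number in (0, 100]; recycled against `p`.
#' @param lambda Initial-abstraction ratio (default 0.2).
#' @return Runoff depth (mm).
#' @export
scs_runoff <- function(p, cn, lambda = 0.2) {
  if (any(p < 0)) stop_af("negative precipitation")
  if (any(cn <= 0 | cn > 100)) stop_af("curve number out of (0, 100]")
  s <- 25400 / cn - 254
  ia <- lambda * s
  q <- ifelse(p <= ia, 0, (p - ia)^2 / (p - ia + s))
  # cn = 100 gives s = 0, ia = 0, q = p exactly
  pmin(q, p)
}

#' Runoff contributed by one catchment cell
#'
#' The SCS runoff of the cell's soil class, scaled by the basin calibration
#' factor and, for cleared-with-mounds cells, the mound multiplier.
#'
#' @param p Daily precipitation (mm).
#' @param cn Curve number of the cell.
#' @param mounds Logical: cleared-with-mounds cell?
#' @param params An [cn_params()] object.
#' @return Runoff depth (mm) delivered by the cell.
#' @export
cell_runoff <- function(p, cn, mounds = FALSE, params = cn_params()) {
  q <- params$calibration_factor * scs_runoff(p, cn, params$lambda)
  q * ifelse(mounds, params$mound_multiplier, 1)
}

#' Fit the basin runoff calibration factor
#'
#' Total-volume ratio estimator: `k = sum(observed) / sum(simulated)` over
#' paired event volumes.
#'
#' @param simulated,observed Paired positive event volumes.
#' @return The calibration factor `k`.
#' @export
fit_calibration_factor <- function(simulated, observed) {
  if (length(simulated) != length(observed) || length(simulated) < 1) {
    stop_af("need paired event volumes (n >= 1)")
  }
  if (any(simulated <= 0) || any(observed <= 0)) stop_af("event volumes must be positive")
  sum(observed) / sum(simulated)
}

#' Compile a basin into flat simulation arrays
#'
#' Precomputes, per terrace, the runoff coefficient against each curve-number
#' class (catchment cell counts times calibration and mound factors), the
#' downslope terrace chain and per-terrace storage/infiltration parameters,
#' so that the daily loop reduces to a few vector operations.
#'
#' @param watershed An `af_watershed`.
#' @param landuse An `af_landuse` from [assign_land_use()].
#' @param params An [cn_params()] object.
#' @param capacity_mm Terrace maximum standing-water column (mm).
#' @param infiltration_mm Named vector: daily infiltration capacity per soil
#'   class (mm/day).
#' @return List of class `af_basin`.
#' @export
compile_basin <- function(watershed, landuse, params = cn_params(),
                          capacity_mm = 150,
                          infiltration_mm = c(R = 6, S = 8, X = 10)) {
  terr <- landuse$terraces
  nt <- nrow(terr)
  classes <- names(params$cn_table)
  soil <- watershed$soil
  mult <- if (landuse$mounds) params$mound_multiplier else 1
  coef <- matrix(0, nt, length(classes), dimnames = list(NULL, classes))
  for (i in seq_len(nt)) {
    cells <- landuse$catchments[[i]]
    cnt <- table(factor(soil[cells], levels = classes))
    coef[i, ] <- as.numeric(cnt) * params$calibration_factor * mult
  }
  # topological order along the downstream chain (upstream terraces first)
  depth <- integer(nt)
  for (i in seq_len(nt)) {
    d <- 0L
    j <- terr$downstream[i]
    while (j > 0L) {
      d <- d + 1L
      j <- terr$downstream[j]
    }
    depth[i] <- d
  }
  structure(
    list(
      n_terraces = nt, coef = coef, cn_values = params$cn_table,
      lambda = params$lambda, downstream = terr$downstream,
      order = order(depth, decreasing = TRUE), chain_depth = depth,
      capacity = rep(capacity_mm, nt),
      infil = unname(infiltration_mm[soil[terr$cell]]),
      crop = terr$crop, farm = terr$farm, terrace_cell = terr$cell,
      params = params, capacity_mm = capacity_mm,
      infiltration_mm = infiltration_mm
    ),
    class = "af_basin"
  )
}

# extend a compiled basin with one more terrace (vineyard expansion)
.basin_add_terrace <- function(basin, watershed, cell, catchment_cells, crop,
                               farm, mounds = TRUE) {
  classes <- names(basin$cn_values)
  cnt <- table(factor(watershed$soil[catchment_cells], levels = classes))
  mult <- if (mounds) basin$params$mound_multiplier else 1
  basin$coef <- rbind(basin$coef,
                      as.numeric(cnt) * basin$params$calibration_factor * mult)
  basin$n_terraces <- basin$n_terraces + 1L
  # new terraces join the chain as most-upstream: route to nearest existing
  # terrace strictly downstream along the channel (larger flow accumulation)
  ds <- 0L
  cand <- which(basin$terrace_cell != cell)
  if (length(cand)) {
    # channel cells: downstream = larger row index in the synthetic valley;
    # fall back to outlet loss when no terrace lies downstream
    nr <- watershed$grid$n_rows
    row_of <- function(i) ((i - 1L) %% nr) + 1L
    rows <- row_of(basin$terrace_cell[cand])
    r0 <- row_of(cell)
    below <- cand[rows > r0]
    if (length(below)) ds <- below[which.min(rows[rows > r0])]
  }
  basin$downstream <- c(basin$downstream, ds)
  basin$capacity <- c(basin$capacity, basin$capacity_mm)
  basin$infil <- c(basin$infil, unname(basin$infiltration_mm[watershed$soil[cell]]))
  basin$crop <- c(basin$crop, crop)
  basin$farm <- c(basin$farm, farm)
  basin$terrace_cell <- c(basin$terrace_cell, cell)
  # chain depths of existing terraces are unchanged by an upstream addition
  depth <- basin$chain_depth %||% integer(basin$n_terraces - 1L)
  new_depth <- if (ds > 0L) depth[ds] + 1L else 0L
  basin$chain_depth <- c(depth, new_depth)
  basin$order <- order(basin$chain_depth, decreasing = TRUE)
  basin
}

#' Initialise the basin water state
#'
#' @param basin An `af_basin`.
#' @return List with per-terrace standing `column` (mm) and seasonal
#'   infiltration `accum` (mm).
#' @export
water_state <- function(basin) {
  list(column = numeric(basin$n_terraces), accum = numeric(basin$n_terraces))
}

#' Advance the basin water state by one day
#'
#' Order of operations: (1) every terrace receives direct rain plus the summed
#' calibrated runoff of its linked catchment cells; (2) evaporation is removed
#' from standing columns (floored at zero); (3) infiltration
#' `min(column, capacity_per_day)` moves from the column to the terrace's
#' seasonal accumulator; (4) columns are capped at storage capacity and
#' overflow cascades to the downslope terrace or is lost at the outlet.
#' Water mass is conserved: inflow = delta(column) + evaporation_actual +
#' infiltration + outlet_loss.
#'
#' @param basin An `af_basin`.
#' @param state A [water_state()] list.
#' @param p Daily precipitation (mm, uniform over the basin).
#' @param e Daily free-water evaporation (mm).
#' @param active Logical vector: terraces currently maintained. Inactive
#'   terraces still route water but accumulate infiltration normally (the
#'   soil does not care); yields are zeroed downstream of this function.
#' @return List: `state` (updated), `ledger` (named numeric: inflow,
#'   evaporation, infiltration, outlet_loss, delta_storage).
#' @export
daily_step <- function(basin, state, p, e, active = NULL) {
  if (p < 0 || e < 0) stop_af("negative precipitation or evaporation")
  q_class <- scs_runoff(rep(p, length(basin$cn_values)), basin$cn_values,
                        basin$lambda)
  inflow <- p + as.vector(basin$coef %*% q_class)
  col0 <- sum(state$column)
  col <- state$column + inflow
  evap_act <- pmin(col, e)
  col <- col - evap_act
  infil <- pmin(col, basin$infil)
  col <- col - infil
  state$accum <- state$accum + infil
  lost <- 0
  ds <- basin$downstream
  for (pass in seq_len(basin$n_terraces + 1L)) {
    over <- pmax(col - basin$capacity, 0)
    if (all(over <= 0)) break
    col <- pmin(col, basin$capacity)
    out <- which(over > 0)
    to_outlet <- out[ds[out] == 0L]
    lost <- lost + sum(over[to_outlet])
    routed <- out[ds[out] > 0L]
    if (length(routed)) {
      add <- rowsum(over[routed], ds[routed])
      ix <- as.integer(rownames(add))
      col[ix] <- col[ix] + add[, 1]
    }
  }
  state$column <- col
  list(
    state = state,
    ledger = c(
      inflow = sum(inflow), evaporation = sum(evap_act),
      infiltration = sum(infil), outlet_loss = lost,
      delta_storage = sum(col) - col0
    )
  )
}

#' Read out and reset the seasonal available-water accumulators
#'
#' Returns the per-terrace total infiltrated water over the season (the
#' "available water storage" driving the annual yield equations) and resets
#' the accumulators for the next year.
#'
#' @param state A [water_state()] list.
#' @return List: `available_mm` (per-terrace mm), `state` (reset).
#' @export
seasonal_available_water <- function(state) {
  out <- state$accum
  state$accum <- numeric(length(state$accum))
  list(available_mm = out, state = state)
}

# fast internal year loop: precomputes the 365 x n_classes runoff matrix and
# runs the same arithmetic as daily_step() without per-call validation.
# Returns available water per terrace plus a mass ledger.
.run_water_year <- function(basin, state, p_vec, e_vec) {
  q_mat <- matrix(0, length(p_vec), length(basin$cn_values))
  for (j in seq_along(basin$cn_values)) {
    q_mat[, j] <- scs_runoff(p_vec, basin$cn_values[[j]], basin$lambda)
  }
  inflow_mat <- q_mat %*% t(basin$coef) + p_vec # 365 x n_terraces
  col <- state$column
  accum <- state$accum
  cap <- basin$capacity
  infil_cap <- basin$infil
  ds <- basin$downstream
  nt <- basin$n_terraces
  lost <- 0
  evap_tot <- 0
  inflow_tot <- 0
  infil_tot <- 0
  col_start <- sum(col)
  rain_day <- p_vec > 0
  has_col <- any(col > 0)
  for (d in seq_along(p_vec)) {
    # dry fast path: no rain and no standing water means nothing changes
    if (!rain_day[d] && !has_col) next
    if (rain_day[d]) {
      inflow <- inflow_mat[d, ]
      inflow_tot <- inflow_tot + sum(inflow)
      col <- col + inflow
    }
    ev <- pmin.int(col, e_vec[d])
    evap_tot <- evap_tot + sum(ev)
    col <- col - ev
    inf <- pmin.int(col, infil_cap)
    col <- col - inf
    accum <- accum + inf
    infil_tot <- infil_tot + sum(inf)
    if (any(col > cap)) {
      for (pass in seq_len(nt + 1L)) {
        over <- col - cap
        over[over < 0] <- 0
        if (!any(over > 0)) break
        col <- pmin.int(col, cap)
        out <- which(over > 0)
        sink_mask <- ds[out] == 0L
        lost <- lost + sum(over[out[sink_mask]])
        routed <- out[!sink_mask]
        if (length(routed)) {
          add <- rowsum(over[routed], ds[routed])
          ix <- as.integer(rownames(add))
          col[ix] <- col[ix] + add[, 1]
        }
      }
    }
    has_col <- any(col > 0)
  }
  state$column <- col
  state$accum <- accum
  list(
    state = state,
    ledger = c(inflow = inflow_tot, evaporation = evap_tot,
               infiltration = infil_tot, outlet_loss = lost,
               delta_storage = sum(col) - col_start)
  )
}
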