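# Water-limited crop yields per terrace: grapevine piecewise-linear response,
# wheat linear response with fallow accounting, pest-inefficiency penalty,
# yield efficiency and grape-to-wine conversion.

#' Crop yield parameters
#'
#' Grapevine yield follows a piecewise-linear water response: zero up to
#' `grape_w_min`, rising linearly to a plateau at `grape_w_opt`, flat to
#' `grape_w_excess`, then declining linearly (waterlogging/rot) at
#' `grape_decline_frac` of the plateau per `grape_decline_mm` of extra water;
#' never negative. Wheat responds linearly (`slope * w + intercept`, floored
#' at 0) and is grown in a fallow pattern. All yields carry a multiplicative
#' pest penalty reflecting ancient pest-control inefficiency.
#'
#' The default grape plateau and wheat slope were calibrated once, on the
#' package's synthetic climate and watershed, so that long-run mean yields
#' land on the historical verification anchors (grape ~339 kg and wheat
#' ~38.3 kg per 0.09-ha terrace, grand-mean yield efficiency ~0.316 across
#' the runoff-ratio sweep); see [calibrate_yield_params()].
#'
#' @param grape_w_min,grape_w_opt,grape_w_excess Breakpoints (mm) of the
#'   grapevine water response.
#' @param grape_y_max Unpenalized plateau yield (kg per 0.09-ha terrace).
#' @param grape_decline_frac,grape_decline_mm Decline of `grape_decline_frac`
#'   of the plateau per `grape_decline_mm` mm beyond `grape_w_excess`.
#' @param wheat_slope,wheat_intercept Wheat full-field response (kg per mm,
#'   kg) before the pest penalty.
#' @param fallow_mode `"half_annual"` (default): every year half the field is
#'   cropped, so annual output and seasonal costs are halved;
#'   `"alternate"`: whole field cropped every other year (zero in fallow
#'   years). Long-run means coincide.
#' @param pest_penalty Fractional yield reduction for ancient pest control
#'   (default 0.10).
#' @param terrace_area_ha Terrace area (default 0.09 ha).
#' @param wine_l_per_kg Wine conversion (liters per kg of grapes, 0.6-0.7).
#' @return List of class `af_yield_params`.
#' @export
yield_params <- function(grape_w_min = 100, grape_w_opt = 343.1,
                         grape_w_excess = 600, grape_y_max = 1087.5,
                         grape_decline_frac = 0.20, grape_decline_mm = 200,
                         wheat_slope = 0.7015, wheat_intercept = -10,
                         fallow_mode = c("half_annual", "alternate"),
                         pest_penalty = 0.10, terrace_area_ha = 0.09,
                         wine_l_per_kg = 0.65) {
  fallow_mode <- match.arg(fallow_mode)
  if (!(grape_w_min < grape_w_opt && grape_w_opt <= grape_w_excess)) {
    stop_af("need grape_w_min < grape_w_opt <= grape_w_excess")
  }
  if (grape_y_max <= 0) stop_af("grape_y_max must be positive")
  if (pest_penalty < 0 || pest_penalty >= 1) stop_af("pest_penalty must be in [0, 1)")
  if (wine_l_per_kg < 0.6 || wine_l_per_kg > 0.7) {
    stop_af("wine_l_per_kg must lie in [0.6, 0.7]")
  }
  structure(
    list(
      grape_w_min = grape_w_min, grape_w_opt = grape_w_opt,
      grape_w_excess = grape_w_excess, grape_y_max = grape_y_max,
      grape_decline_frac = grape_decline_frac,
      grape_decline_mm = grape_decline_mm,
      wheat_slope = wheat_slope, wheat_intercept = wheat_intercept,
      fallow_mode = fallow_mode, pest_penalty = pest_penalty,
      terrace_area_ha = terrace_area_ha, wine_l_per_kg = wine_l_per_kg
    ),
    class = "af_yield_params"
  )
}

#' Grapevine yield from seasonal available water
#'
#' @param w Seasonal available water (mm, >= 0); vectorized.
#' @param params An [yield_params()] object.
#' @return Yield in kg per terrace (pest penalty applied).
#' @export
grape_yield <- function(w, params = yield_params()) {
  if (any(w < 0)) stop_af("negative available water")
  p <- params
  rise <- pmin(pmax((w - p$grape_w_min) / (p$grape_w_opt - p$grape_w_min), 0), 1)
  decline <- pmax(0, 1 - p$grape_decline_frac *
                    pmax(w - p$grape_w_excess, 0) / p$grape_decline_mm)
  (1 - p$pest_penalty) * p$grape_y_max * pmin(rise, decline)
}

#' Wheat yield from seasonal available water
#'
#' In the default `half_annual` fallow mode half the field is cropped every
#' year, so the annual output is half the full-field linear response; in
#' `alternate` mode the whole field yields in cropped years and nothing in
#' fallow years.
#'
#' @param w Seasonal available water (mm, >= 0); vectorized.
#' @param params An [yield_params()] object.
#' @param fallow_phase Logical: is this a fallow year (`alternate` mode only)?
#' @return Yield in kg per terrace (pest penalty applied).
#' @export
wheat_yield <- function(w, params = yield_params(), fallow_phase = FALSE) {
  if (any(w < 0)) stop_af("negative available water")
  full <- (1 - params$pest_penalty) *
    pmax(0, params$wheat_slope * w + params$wheat_intercept)
  if (params$fallow_mode == "half_annual") {
    0.5 * full
  } else if (fallow_phase) {
    rep(0, length(w))
  } else {
    full
  }
}

#' Yield efficiency
#'
#' Realized yield as a fraction of the pest-adjusted attainable maximum
#' (`(1 - pest) * grape_y_max` for grapes), clipped to `[0, 1]`. A vineyard
#' with perfect water supply scores 1.
#'
#' @param y Yield (kg per terrace); vectorized.
#' @param params An [yield_params()] object.
#' @param crop `"grape"` (the default; wheat efficiency uses the full-field
#'   attainable response at the optimum and is rarely needed).
#' @return Dimensionless efficiency in `[0, 1]`.
#' @export
yield_efficiency <- function(y, params = yield_params(), crop = "grape") {
  denom <- (1 - params$pest_penalty) * params$grape_y_max
  pmin(pmax(y / denom, 0), 1)
}

#' Convert grape mass to wine volume
#'
#' @param y_total_kg Grape yield (kg).
#' @param l_per_kg Conversion (liters of wine per kg of grapes, default 0.65).
#' @return Liters of wine.
#' @export
wine_volume <- function(y_total_kg, l_per_kg = 0.65) {
  if (any(y_total_kg < 0)) stop_af("negative grape mass")
  l_per_kg * y_total_kg
}

#' Calibrate the yield-curve defaults against historical anchors
#'
#' Fits (a) the grapevine plateau position `grape_w_opt` so that the
#' grand-mean yield efficiency over the supplied per-ratio water samples
#' equals `target_efficiency`, (b) `grape_y_max` so that the mean grape yield
#' at `anchor_ratio` equals `target_grape_kg`, and (c) `wheat_slope` so the
#' long-run mean wheat yield equals `target_wheat_kg`. The water samples are
#' annual available-water draws obtained by simulating the basin under the
#' synthetic climate (see the methods vignette).
#'
#' @param water_by_ratio Named list: runoff ratio -> numeric vector of annual
#'   available water (mm) for grape terraces.
#' @param wheat_water Numeric vector of annual available water (mm) for wheat
#'   terraces.
#' @param anchor_ratio Ratio (name in `water_by_ratio`) anchoring the grape
#'   mass target.
#' @param target_grape_kg,target_wheat_kg,target_efficiency Anchors.
#' @param params Starting [yield_params()].
#' @return A calibrated `af_yield_params` object.
#' @export
calibrate_yield_params <- function(water_by_ratio, wheat_water,
                                   anchor_ratio = "20",
                                   target_grape_kg = 339,
                                   target_wheat_kg = 38.3,
                                   target_efficiency = 0.316,
                                   params = yield_params()) {
  eff_given_wopt <- function(w_opt) {
    p <- params
    p$grape_w_opt <- w_opt
    p$grape_w_excess <- max(w_opt, p$grape_w_excess)
    effs <- vapply(water_by_ratio, function(w) {
      mean(grape_yield(w, p)) / ((1 - p$pest_penalty) * p$grape_y_max)
    }, numeric(1))
    mean(effs)
  }
  f <- function(w_opt) eff_given_wopt(w_opt) - target_efficiency
  lo <- params$grape_w_min + 10
  hi <- 3000
  w_opt <- if (f(lo) < 0) lo else stats::uniroot(f, c(lo, hi))$root
  params$grape_w_opt <- w_opt
  params$grape_w_excess <- max(w_opt, params$grape_w_excess)
  w20 <- water_by_ratio[[anchor_ratio]]
  eff20 <- mean(grape_yield(w20, params)) /
    ((1 - params$pest_penalty) * params$grape_y_max)
  params$grape_y_max <- target_grape_kg / ((1 - params$pest_penalty) * eff20)
  g <- function(slope) {
    p <- params
    p$wheat_slope <- slope
    mean(wheat_yield(wheat_water, p)) - target_wheat_kg
  }
  params$wheat_slope <- stats::uniroot(g, c(0.01, 10))$root
  params
}
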