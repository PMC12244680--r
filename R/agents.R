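# Farm decision-making at annual resolution: success/failure classification,
# loss-aversion yield memory, vineyard expansion and wheat reassessment.

#' Outcome thresholds per crop
#'
#' Grapevine: below 270 kg/terrace is a failure, above 400 kg a success.
#' Wheat: under 10 kg a failure, above 20 kg a success. Comparisons are
#' strict, so boundary values are moderate.
#'
#' @return Nested list of `failure_below` / `success_above` per crop.
#' @export
outcome_thresholds <- function() {
  list(
    grape = list(failure_below = 270, success_above = 400),
    wheat = list(failure_below = 10, success_above = 20)
  )
}

#' Classify a season outcome
#'
#' @param crop `"grape"` or `"wheat"`.
#' @param yield_kg Mean yield per terrace (kg).
#' @param thresholds See [outcome_thresholds()].
#' @return `"failure"`, `"moderate"` or `"success"`.
#' @export
classify_outcome <- function(crop, yield_kg, thresholds = outcome_thresholds()) {
  th <- thresholds[[crop]]
  if (is.null(th)) stop_af("unknown crop '%s'", crop)
  if (yield_kg < th$failure_below) {
    "failure"
  } else if (yield_kg > th$success_above) {
    "success"
  } else {
    "moderate"
  }
}

#' Create an empty yield memory
#'
#' @param window Rolling window length in years (default 5).
#' @return List of class `af_memory`: `outcomes` (most recent last) and
#'   `consec_failures`.
#' @export
new_yield_memory <- function(window = 5) {
  structure(list(outcomes = character(0), consec_failures = 0L,
                 window = as.integer(window)),
            class = "af_memory")
}

#' Append a season outcome to a yield memory
#'
#' The oldest entry is evicted beyond the window; the consecutive-failure
#' counter increments on failure and resets to zero otherwise.
#'
#' @param memory An [new_yield_memory()] object.
#' @param outcome `"failure"`, `"moderate"` or `"success"`.
#' @return The updated memory.
#' @export
update_memory <- function(memory, outcome) {
  if (!outcome %in% c("failure", "moderate", "success")) {
    stop_af("unknown outcome '%s'", outcome)
  }
  memory$outcomes <- utils::tail(c(memory$outcomes, outcome), memory$window)
  memory$consec_failures <- if (outcome == "failure") memory$consec_failures + 1L else 0L
  memory
}

#' Decision policy parameters
#'
#' @param f_max Consecutive failures at/beyond which expansion is blocked
#'   (default 2).
#' @param expansion_step Maximum new vineyard terraces per farm per year.
#' @return List of class `af_policy`.
#' @export
decision_policy <- function(f_max = 2, expansion_step = 1) {
  if (f_max < 1 || expansion_step < 1) stop_af("policy parameters must be positive")
  list(f_max = as.integer(f_max), expansion_step = as.integer(expansion_step))
}

#' Annual farm decision
#'
#' Pure function of the grape outcome, the yield memory and the ledger:
#' success prompts vineyard expansion when the establishment cost is
#' affordable and the farm is not risk-locked (consecutive failures below
#' `f_max`); a moderate year expands only on a failure-free memory window;
#' failure triggers reassessment of the wheat fields. Unaffordable expansion
#' degrades to hold.
#'
#' @param outcome Grape outcome for the season.
#' @param memory The farm's grape [new_yield_memory()] after the update.
#' @param storage_kg Wheat storage after settlement (kg).
#' @param expansion_cost_kg Full cost of establishing one new vineyard
#'   terrace (construction + planting).
#' @param policy An [decision_policy()].
#' @return One of `"expand_vineyard"`, `"hold"`, `"reassess_wheat"`.
#' @export
decide <- function(outcome, memory, storage_kg, expansion_cost_kg,
                   policy = decision_policy()) {
  afford <- storage_kg >= expansion_cost_kg
  blocked <- memory$consec_failures >= policy$f_max
  if (outcome == "failure") {
    "reassess_wheat"
  } else if (outcome == "success") {
    if (afford && !blocked) "expand_vineyard" else "hold"
  } else {
    if (afford && !blocked && !("failure" %in% memory$outcomes)) {
      "expand_vineyard"
    } else {
      "hold"
    }
  }
}
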