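#' Itemized cost of one cycle for one woman
#'
#' Sums the payer-perspective components accrued during a cycle: screening
#' (mammogram + coordination, plus the per-screen AI cost under AI
#' modalities) when a screen was attended; biopsy when one was done;
#' stage-specific treatment cost (year-1 in the diagnosis year,
#' years-2-to-5 annually while `years_since_dx` is 1-4); and the annual
#' survivor-care cost in the survivor state. Undetected disease costs
#' nothing - the payer only sees diagnosed cancer.
#'
#' @param clinical state code from [STATES].
#' @param detected logical.
#' @param years_since_dx integer.
#' @param ev a `screen_event` (or `NULL` when no screen occurred).
#' @param modality the screening modality in force (for the AI cost).
#' @param cfg an `msim_config`.
#' @return list with `cost` (total) and `components` (named numeric vector:
#'   screening, ai, biopsy, treatment, survivor); the total always equals
#'   the sum of the components.
#' @export
cycle_cost <- function(clinical, detected, years_since_dx, ev = NULL,
                       modality = "NONE", cfg) {
  ec <- cfg$econ
  comp <- c(screening = 0, ai = 0, biopsy = 0, treatment = 0, survivor = 0)
  if (!is.null(ev) && isTRUE(ev$attended)) {
    comp[["screening"]] <- ec$cost_mammogram + ec$cost_coordination
    if (modality %in% c("AI_CONCURRENT", "AI_TRIAGE"))
      comp[["ai"]] <- ec$cost_ai_per_screen
  }
  if (!is.null(ev) && isTRUE(ev$biopsy_done))
    comp[["biopsy"]] <- ec$cost_biopsy
  if (detected && clinical >= STATES[["DCIS"]] &&
      clinical <= STATES[["STAGE_IV"]]) {
    if (years_since_dx == 0L)
      comp[["treatment"]] <- ec$tx_cost_y1[[stage_of(clinical)]]
    else if (years_since_dx <= 4L)
      comp[["treatment"]] <- ec$tx_cost_y2to5[[stage_of(clinical)]]
  }
  if (clinical == STATES[["SURVIVOR"]])
    comp[["survivor"]] <- ec$cost_survivor_annual
  list(cost = sum(comp), components = comp)
}

#' Utility weight of one cycle for one woman
#'
#' Healthy women receive the age-band population norm; DCIS and invasive
#' stages receive their state utilities; survivors receive the age-matched
#' healthy norm (default policy) or a fixed value; the dead receive 0.
#' False-positive anxiety and biopsy disutilities are subtracted once in
#' the cycle of the event, and the result is floored at 0.
#'
#' @inheritParams cycle_cost
#' @param age integer age in years.
#' @return the cycle's QALY weight in \[0, 1\].
#' @export
cycle_utility <- function(clinical, age, ev = NULL, cfg) {
  ut <- cfg$utils
  u <- if (clinical == STATES[["HEALTHY"]])
    ab_lookup(ut$u_healthy_by_age, age)
  else if (clinical >= STATES[["DCIS"]] && clinical <= STATES[["STAGE_IV"]])
    ut$u_state[[stage_of(clinical)]]
  else if (clinical == STATES[["SURVIVOR"]]) {
    if (ut$u_survivor_policy == "age_matched_healthy")
      ab_lookup(ut$u_healthy_by_age, age)
    else ut$u_survivor_fixed
  } else 0
  if (!is.null(ev)) {
    if (identical(ev$result, "FALSE_POS")) u <- u - ut$disutil_fp
    if (isTRUE(ev$biopsy_done)) u <- u - ut$disutil_biopsy
  }
  max(u, 0)
}

#' Discount factor for an annual cycle
#'
#' End-of-cycle discounting with the first cycle undiscounted:
#' `(1 + rate)^-(cycle - 1)`. Set `first_cycle_undiscounted = FALSE` to
#' discount from the first cycle (`(1 + rate)^-cycle`).
#'
#' @param cycle integer cycle index, starting at 1.
#' @param rate annual discount rate in \[0, 1).
#' @param first_cycle_undiscounted logical convention switch.
#' @return numeric discount factor(s).
#' @export
discount_factor <- function(cycle, rate, first_cycle_undiscounted = TRUE) {
  if (any(cycle < 1)) stop("cycle must be >= 1")
  expo <- if (first_cycle_undiscounted) cycle - 1 else cycle
  (1 + rate)^(-expo)
}
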