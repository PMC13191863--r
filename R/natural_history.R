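#' Clinical state codes
#'
#' The mutually exclusive health states of the natural-history model, as an
#' integer coding used throughout the engine: healthy, ductal carcinoma in
#' situ (DCIS), invasive stages I-IV, post-treatment survivor, death from
#' breast cancer, and death from other causes. The two death states are
#' absorbing; the survivor state is reachable only from detected (treated)
#' disease after five years post-diagnosis.
#'
#' @format a named integer vector.
#' @export
STATES <- c(HEALTHY = 1L, DCIS = 2L, STAGE_I = 3L, STAGE_II = 4L,
            STAGE_III = 5L, STAGE_IV = 6L, SURVIVOR = 7L,
            DEAD_BC = 8L, DEAD_OTHER = 9L)

state_name <- function(code) names(STATES)[code]

# stage index 1..5 = DCIS, I, II, III, IV for a clinical code 2..6
stage_of <- function(clin) clin - 1L

#' One-cycle transition distribution for an individual
#'
#' Returns the exact categorical distribution over next-cycle individual
#' states implied by the sequential competing-event scheme. Within a cycle
#' the events are drawn conditionally in a fixed order: (1) other-cause
#' death at the age-band all-cause probability, applied to every living
#' state; (2) breast-cancer death for *detected* stage IV at the year-1
#' probability in the diagnosis year and the years-2-5 probability while
#' `years_since_dx <= 4`; (3) symptomatic diagnosis for undetected invasive
#' disease (stage IV with probability 1: metastatic disease is taken to be
#' clinically evident); (4) regression or progression for undetected
#' DCIS/invasive stages; (5) relapse to detected stage IV for treated
#' stages I-III at the year-specific relapse probability; (6) detected
#' non-relapsing states advance the time-since-diagnosis clock, entering
#' survivorship at the start of year 6. Detected (treated) disease does not
#' progress through stages: its only disease exit is relapse.
#'
#' @param clinical a state code from [STATES] (or its name).
#' @param detected logical; has the disease been diagnosed?
#' @param years_since_dx integer >= 0, meaningful when `detected`.
#' @param age integer age in years.
#' @param cfg an `msim_config`.
#' @return a data.frame with columns `clinical`, `detected`,
#'   `years_since_dx`, `prob` (a `transition_row`): the support of the next
#'   state distribution in the documented fixed order, probabilities
#'   summing to 1.
#' @export
transition_row <- function(clinical, detected, years_since_dx, age, cfg) {
  if (is.character(clinical)) clinical <- STATES[[clinical]]
  nh <- cfg$nat_hist; mt <- cfg$mortality
  out <- list()
  emit <- function(clin, det, ysd, p) {
    if (p > 0 || length(out) == 0L)
      out[[length(out) + 1L]] <<- data.frame(
        clinical = clin, detected = det, years_since_dx = ysd, prob = p)
  }

  if (clinical %in% c(STATES[["DEAD_BC"]], STATES[["DEAD_OTHER"]])) {
    emit(clinical, FALSE, 0L, 1)
    return(finish_row(out))
  }

  q <- ab_lookup(mt$allcause_by_age, age)
  emit(STATES[["DEAD_OTHER"]], FALSE, 0L, q)
  s <- 1 - q

  adv <- function(ysd) ysd + 1L                     # post-treatment clock
  to_next <- function(ysd) if (adv(ysd) >= 5L) STATES[["SURVIVOR"]] else NA

  if (clinical == STATES[["HEALTHY"]]) {
    p_on <- ab_lookup(nh$onset_by_age, age)
    emit(STATES[["DCIS"]], FALSE, 0L, s * p_on)
    emit(STATES[["HEALTHY"]], FALSE, 0L, s * (1 - p_on))
  } else if (clinical == STATES[["SURVIVOR"]]) {
    emit(STATES[["SURVIVOR"]], TRUE, years_since_dx, s)
  } else if (!detected) {
    if (clinical == STATES[["DCIS"]]) {
      emit(STATES[["HEALTHY"]], FALSE, 0L, s * nh$p_dcis_regress)
      emit(STATES[["STAGE_I"]], FALSE, 0L, s * nh$p_dcis_to_I)
      emit(STATES[["DCIS"]], FALSE, 0L,
           s * (1 - nh$p_dcis_regress - nh$p_dcis_to_I))
    } else if (clinical == STATES[["STAGE_IV"]]) {
      # metastatic disease is diagnosed with certainty this cycle
      p_dx <- nh$p_sympt_dx_IV
      emit(STATES[["STAGE_IV"]], TRUE, 0L, s * p_dx)
      emit(STATES[["STAGE_IV"]], FALSE, 0L, s * (1 - p_dx))
    } else {
      p_dx <- switch(state_name(clinical),
                     STAGE_I = nh$p_sympt_dx_I,
                     STAGE_II = nh$p_sympt_dx_II,
                     STAGE_III = nh$p_sympt_dx_III)
      p_pr <- switch(state_name(clinical),
                     STAGE_I = nh$p_I_to_II,
                     STAGE_II = nh$p_II_to_III,
                     STAGE_III = nh$p_III_to_IV)
      emit(clinical, TRUE, 0L, s * p_dx)
      emit(clinical + 1L, FALSE, 0L, s * (1 - p_dx) * p_pr)
      emit(clinical, FALSE, 0L, s * (1 - p_dx) * (1 - p_pr))
    }
  } else {
    ysd <- years_since_dx
    if (clinical == STATES[["STAGE_IV"]]) {
      p_bc <- if (ysd == 0L) mt$p_bc_death_stageIV_y1
              else if (ysd <= 4L) mt$p_bc_death_stageIV_y2to5 else 0
      emit(STATES[["DEAD_BC"]], FALSE, 0L, s * p_bc)
      nxt <- to_next(ysd)
      if (is.na(nxt)) emit(STATES[["STAGE_IV"]], TRUE, adv(ysd), s * (1 - p_bc))
      else emit(nxt, TRUE, adv(ysd), s * (1 - p_bc))
    } else if (clinical %in% STATES[c("STAGE_I", "STAGE_II", "STAGE_III")]) {
      stg <- state_name(clinical)
      stg <- c(STAGE_I = "I", STAGE_II = "II", STAGE_III = "III")[[stg]]
      p_rel <- if (ysd == 0L) mt$relapse_y1[[stg]]
               else if (ysd <= 4L) mt$relapse_y2to5[[stg]] else 0
      emit(STATES[["STAGE_IV"]], TRUE, 0L, s * p_rel)
      nxt <- to_next(ysd)
      if (is.na(nxt)) emit(clinical, TRUE, adv(ysd), s * (1 - p_rel))
      else emit(nxt, TRUE, adv(ysd), s * (1 - p_rel))
    } else if (clinical == STATES[["DCIS"]]) {
      # treated DCIS: no progression, no relapse block
      nxt <- to_next(ysd)
      if (is.na(nxt)) emit(STATES[["DCIS"]], TRUE, adv(ysd), s)
      else emit(nxt, TRUE, adv(ysd), s)
    } else {
      stop("unknown detected state: ", clinical)
    }
  }
  finish_row(out)
}

finish_row <- function(out) {
  row <- do.call(rbind, out)
  if (abs(sum(row$prob) - 1) > 1e-12)
    stop("internal error: transition row does not sum to 1")
  class(row) <- c("transition_row", class(row))
  row
}

#' Sample a transition from a categorical row
#'
#' Inverse-CDF draw over the fixed outcome ordering of a
#' [transition_row()]: outcome `k` is chosen when the cumulative
#' probability first exceeds `u`. `u = 0` therefore selects the first
#' outcome with positive probability.
#'
#' @param row a `transition_row`.
#' @param u a uniform deviate in \[0, 1).
#' @return a one-row data.frame (the selected next state).
#' @export
sample_transition <- function(row, u) {
  stopifnot(inherits(row, "transition_row"), u >= 0, u < 1)
  if (any(row$prob < 0) || abs(sum(row$prob) - 1) > 1e-9)
    stop("invalid transition row")
  k <- findInterval(u, cumsum(row$prob), left.open = TRUE) + 1L
  k <- min(k, nrow(row))
  row[k, c("clinical", "detected", "years_since_dx")]
}

#' Counterfactual overdiagnosis classification of a detected DCIS
#'
#' When a DCIS is screen-detected, simulates the counterfactual *untreated*
#' trajectory forward from the moment of detection on an independent child
#' random stream: each year the woman may die of other causes, her lesion
#' may regress to healthy, or it may progress to invasive stage I. The
#' detection is classified as overdiagnosis when the counterfactual lesion
#' regresses or the woman dies without the lesion ever becoming invasive -
#' i.e. the cancer would never have surfaced in her lifetime. Used for
#' reporting only; it does not alter the simulated trajectory.
#'
#' @param age integer age at detection.
#' @param cfg an `msim_config`.
#' @param child_seed integer seed for the independent counterfactual stream.
#' @return logical: `TRUE` if the detection is an overdiagnosis.
#' @export
classify_overdiagnosis <- function(age, cfg, child_seed) {
  nh <- cfg$nat_hist; mt <- cfg$mortality
  set.seed(child_seed)
  a <- age
  repeat {
    if (a > 120L) return(TRUE)            # outlived the lesion
    q <- ab_lookup(mt$allcause_by_age, a)
    if (stats::runif(1L) < q) return(TRUE)      # died, never invasive
    u <- stats::runif(1L)
    if (u < nh$p_dcis_regress) return(TRUE)     # regressed
    if (u < nh$p_dcis_regress + nh$p_dcis_to_I) return(FALSE)  # invaded
    a <- a + 1L
  }
}
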