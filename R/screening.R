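#' Screening strategy registry
#'
#' The ten evaluated strategies: no screening; radiologist-only mammography
#' at annual/biennial/triennial intervals (`sim_mammo_D1..D3`); mammography
#' with concurrent AI and radiologist reading, positive if either reader
#' flags the exam (`sim_mammo_AI_D1..D3`); and AI triage where only
#' AI-positive exams are reviewed and confirmed by a radiologist
#' (`sim_mammo_AIR_D1..D3`). All schedules run from age 40 through age 75.
#' The per-modality stage-specific sensitivity/specificity blocks already
#' encode the combined reading rule, so the modality performance is used
#' verbatim rather than re-derived from a standalone AI operating point
#' (see [compose_readers()] for the exploratory helper).
#'
#' @param id a strategy id string, e.g. `"sim_mammo_AI_D1"`.
#' @return a `strategy_spec` list with fields `id`, `modality`
#'   (`NONE`, `MAMMO`, `AI_CONCURRENT`, `AI_TRIAGE`), `interval_years`,
#'   `start_age`, `stop_age`.
#' @export
screening_strategy <- function(id) {
  reg <- strategy_registry()
  if (!id %in% reg$id) stop("unknown strategy id: ", id)
  r <- reg[reg$id == id, ]
  structure(list(id = r$id, modality = r$modality,
                 interval_years = r$interval_years,
                 start_age = r$start_age, stop_age = r$stop_age),
            class = "strategy_spec")
}

#' @rdname screening_strategy
#' @export
strategy_registry <- function() {
  data.frame(
    id = c("sim_noscreening",
           paste0("sim_mammo_D", 1:3),
           paste0("sim_mammo_AI_D", 1:3),
           paste0("sim_mammo_AIR_D", 1:3)),
    modality = c("NONE", rep("MAMMO", 3), rep("AI_CONCURRENT", 3),
                 rep("AI_TRIAGE", 3)),
    interval_years = c(1L, 1:3, 1:3, 1:3),
    start_age = 40L, stop_age = 75L,
    stringsAsFactors = FALSE)
}

#' @export
print.strategy_spec <- function(x, ...) {
  if (x$modality == "NONE") cat(sprintf("<%s: no screening>\n", x$id))
  else cat(sprintf("<%s: %s every %d yr, ages %d-%d>\n", x$id, x$modality,
                   x$interval_years, x$start_age, x$stop_age))
  invisible(x)
}

#' Is a screen due at a given age?
#'
#' A screen is due when the strategy screens at all, the age lies within
#' the screening window, and the age falls on the strategy's interval grid
#' anchored at the start age.
#'
#' @param age integer age in years (vectorized).
#' @param strategy a `strategy_spec`.
#' @return logical vector.
#' @export
is_screen_due <- function(age, strategy) {
  if (strategy$modality == "NONE") return(rep(FALSE, length(age)))
  age >= strategy$start_age & age <= strategy$stop_age &
    (age - strategy$start_age) %% strategy$interval_years == 0L
}

#' Outcome of one screening round for one woman
#'
#' Draws attendance, the imaging result under the strategy's modality
#' (stage-specific sensitivity for diseased women, 1 - specificity for
#' healthy women), the biopsy referral (every true positive; false
#' positives with the configured false-positive-to-biopsy probability),
#' and biopsy confirmation. This is the scalar reference implementation of
#' the screening pathway; [run_cohort()] applies the identical logic
#' vectorized.
#'
#' @param clinical state code from [STATES]; must be alive and undetected.
#' @param age integer age.
#' @param strategy a `strategy_spec`.
#' @param cfg an `msim_config`.
#' @param u optional numeric vector of three uniforms (attendance, test,
#'   biopsy) for deterministic replay; drawn from the session RNG if `NULL`.
#' @return a list (`screen_event`): `attended`, `result` (one of `NOT_DUE`,
#'   `NOT_ATTENDED`, `TRUE_POS`, `FALSE_POS`, `TRUE_NEG`, `FALSE_NEG`),
#'   `biopsy_done`, `detected` (biopsy-confirmed detection).
#' @export
screen_outcome <- function(clinical, age, strategy, cfg, u = NULL) {
  if (clinical %in% STATES[c("DEAD_BC", "DEAD_OTHER")])
    stop("screen_outcome called on a dead individual")
  if (is.null(u)) u <- stats::runif(3L)
  ev <- list(attended = FALSE, result = "NOT_DUE", biopsy_done = FALSE,
             detected = FALSE)
  if (!is_screen_due(age, strategy)) return(ev)
  if (u[1L] >= cfg$settings$intake_rate) {
    ev$result <- "NOT_ATTENDED"
    return(ev)
  }
  ev$attended <- TRUE
  perf <- cfg$tests[[strategy$modality]]
  diseased <- clinical >= STATES[["DCIS"]] && clinical <= STATES[["STAGE_IV"]]
  if (diseased) {
    sens <- perf$sens_by_stage[[stage_of(clinical)]]
    if (u[2L] < sens) {
      ev$result <- "TRUE_POS"
      ev$biopsy_done <- TRUE
      ev$detected <- u[3L] < cfg$biopsy$sensitivity
    } else ev$result <- "FALSE_NEG"
  } else {
    if (u[2L] < 1 - perf$specificity) {
      ev$result <- "FALSE_POS"
      ev$biopsy_done <- u[3L] < cfg$screening$p_fp_biopsy
    } else ev$result <- "TRUE_NEG"
  }
  ev
}

#' Apply a confirmed detection to an individual state
#'
#' Marks the disease as detected at its current stage and resets the
#' time-since-diagnosis clock. Only biopsy-confirmed true positives may be
#' applied; at baseline biopsy specificity is 1, so a false positive can
#' never be "detected".
#'
#' @param state a list with `clinical`, `detected`, `years_since_dx`.
#' @param ev a `screen_event` from [screen_outcome()].
#' @return the updated state list.
#' @export
apply_detection <- function(state, ev) {
  if (!identical(ev$result, "TRUE_POS") || !isTRUE(ev$detected))
    stop("detection can only be applied to a biopsy-confirmed true positive")
  state$detected <- TRUE
  state$years_since_dx <- 0L
  state
}

#' Compose two independent readers into a combined operating point
#'
#' Exploratory helper for scenario analysis: combines a radiologist and an
#' AI operating point under the concurrent rule (positive if either reader
#' is positive) or the triage rule (positive only if the AI flags and the
#' radiologist confirms), assuming conditionally independent reads. The
#' baseline analysis does not use this - the packaged per-modality blocks
#' already encode the combined rules.
#'
#' @param sens_rad,spec_rad radiologist sensitivity/specificity.
#' @param sens_ai,spec_ai AI sensitivity/specificity.
#' @param rule `"concurrent"` (OR) or `"triage"` (AND).
#' @return list with `sensitivity` and `specificity` of the combination.
#' @export
compose_readers <- function(sens_rad, spec_rad, sens_ai, spec_ai,
                            rule = c("concurrent", "triage")) {
  rule <- match.arg(rule)
  if (rule == "concurrent") {
    list(sensitivity = 1 - (1 - sens_rad) * (1 - sens_ai),
         specificity = spec_rad * spec_ai)
  } else {
    list(sensitivity = sens_rad * sens_ai,
         specificity = 1 - (1 - spec_rad) * (1 - spec_ai))
  }
}
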