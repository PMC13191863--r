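#' Simulate a screened cohort under one strategy
#'
#' The microsimulation driver. Each of `n_individuals` women enters healthy
#' at the start age and is followed for `n_cycles` annual cycles. Within a
#' cycle the order of operations is: screening at the start of the cycle
#' (attendance, imaging, biopsy, detection - a cancer detected this cycle
#' accrues its year-1 treatment cost this cycle), then the cycle's cost and
#' utility ledger, then the natural-history transition at the end of the
#' cycle. Costs and QALYs are discounted per cycle and summed per woman.
#'
#' All randomness is pre-drawn from `seed` as per-purpose uniform matrices
#' (in the fixed order: attendance, imaging, biopsy, other-cause death,
#' breast-cancer death, symptomatic diagnosis, progression, relapse), so a
#' given `(cfg, strategy, seed)` is bit-reproducible and different
#' strategies run under the *same seed* share every woman's life-course
#' randomness (common random numbers): strategy contrasts are paired.
#'
#' The per-cycle transition applies, vectorized, exactly the sequential
#' competing-event scheme of [transition_row()], using one independent
#' uniform per event class; the resulting next-state distribution is
#' identical.
#'
#' @param cfg an `msim_config`.
#' @param strategy a `strategy_spec` or strategy id string.
#' @param seed integer seed for this run.
#' @param n optional override of `cfg$settings$n_individuals`.
#' @param classify_overdx logical; classify screen-detected DCIS against
#'   the untreated counterfactual (reporting only; disable for speed in
#'   large parameter sweeps).
#' @param trace logical; keep per-woman per-cycle state/cost/utility
#'   matrices in the result.
#' @return an `msim_cohort` with per-strategy mean discounted cost and
#'   QALYs, epidemiological counts per 10,000 women (breast-cancer deaths,
#'   incident invasive cases, overdiagnosed DCIS), screen/biopsy/false
#'   positive counts, per-age-band incidence ingredients, and the
#'   stage-at-diagnosis tally.
#' @export
run_cohort <- function(cfg, strategy, seed, n = NULL,
                       classify_overdx = TRUE, trace = FALSE) {
  if (is.character(strategy)) strategy <- screening_strategy(strategy)
  validate_config(cfg)
  n <- as.integer(n %||% cfg$settings$n_individuals)
  TT <- as.integer(cfg$settings$n_cycles)
  set.seed(as.integer(seed))
  U <- draw_uniforms(n, TT)
  run_cohort_impl(cfg, strategy, seed = as.integer(seed), U = U, n = n,
                  classify_overdx = classify_overdx, trace = trace)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-purpose uniform matrices, drawn in a fixed documented order
draw_uniforms <- function(n, TT) {
  list(att = matrix(stats::runif(n * TT), n, TT),
       scr = matrix(stats::runif(n * TT), n, TT),
       bx  = matrix(stats::runif(n * TT), n, TT),
       dth = matrix(stats::runif(n * TT), n, TT),
       bcd = matrix(stats::runif(n * TT), n, TT),
       sym = matrix(stats::runif(n * TT), n, TT),
       prg = matrix(stats::runif(n * TT), n, TT),
       rel = matrix(stats::runif(n * TT), n, TT))
}

run_cohort_impl <- function(cfg, strategy, seed, U, n,
                            classify_overdx = TRUE, trace = FALSE) {
  st <- cfg$settings; nh <- cfg$nat_hist; mt <- cfg$mortality; ec <- cfg$econ
  TT <- as.integer(st$n_cycles)
  ages <- st$start_age + seq_len(TT) - 1L

  # per-cycle scalars (the cohort is a single birth-year: one age per cycle)
  q_mort  <- ab_lookup(mt$allcause_by_age, ages)
  p_onset <- ab_lookup(nh$onset_by_age, ages)
  u_healthy <- ab_lookup(cfg$utils$u_healthy_by_age, ages)
  fcu <- !isTRUE(ec$discount_first_cycle)
  dfc <- discount_factor(seq_len(TT), ec$discount_cost, fcu)
  dfe <- discount_factor(seq_len(TT), ec$discount_effect, fcu)

  screening_on <- strategy$modality != "NONE"
  if (screening_on) {
    perf <- cfg$tests[[strategy$modality]]
    sens_by_clin <- c(NA, perf$sens_by_stage)[seq_len(6L)]  # index by clin 2..6
    fp_rate <- 1 - perf$specificity
    ai_cost <- if (strategy$modality %in% c("AI_CONCURRENT", "AI_TRIAGE"))
      ec$cost_ai_per_screen else 0
    screen_cost <- ec$cost_mammogram + ec$cost_coordination + ai_cost
    due <- is_screen_due(ages, strategy)
  } else due <- rep(FALSE, TT)

  u_state <- cfg$utils$u_state        # DCIS, I, II, III, IV
  surv_age_matched <- cfg$utils$u_survivor_policy == "age_matched_healthy"
  tx1 <- ec$tx_cost_y1; tx25 <- ec$tx_cost_y2to5
  rel1 <- mt$relapse_y1; rel25 <- mt$relapse_y2to5

  clin <- rep.int(STATES[["HEALTHY"]], n)
  det  <- rep.int(FALSE, n)
  ysd  <- rep.int(0L, n)
  # exploratory alternative reading of the initial stage distribution:
  # seed a fraction of the cohort with undetected prevalent invasive disease
  # (deterministic proportional assignment; off by default)
  if (isTRUE(st$seed_prevalent_disease)) {
    frac <- st$prevalent_fraction %||% 0
    m <- round(n * frac)
    if (m > 0) {
      counts <- diff(round(cumsum(c(0, cfg$init_stage_distribution)) * m))
      clin[seq_len(sum(counts))] <- rep.int(STATES[["STAGE_I"]] + 0:3, counts)
    }
  }
  ever_inv <- clin >= STATES[["STAGE_I"]] & clin <= STATES[["STAGE_IV"]]
  overdx   <- rep.int(FALSE, n)
  disc_cost <- numeric(n); disc_qaly <- numeric(n)

  n_bc_death <- 0L
  inc_events <- integer(TT)   # new invasive entries per cycle
  py_at_risk <- numeric(TT)   # person-years alive & invasive-free per cycle
  n_screens <- 0L; n_biopsies <- 0L; n_fp <- 0L; n_screen_det <- 0L
  stage_at_dx <- c(DCIS = 0L, I = 0L, II = 0L, III = 0L, IV = 0L)
  child_seeds <- (as.numeric(seed) + 1000003 * seq_len(n)) %% 2147483647

  if (trace) {
    tr_state <- matrix(NA_integer_, n, TT)
    tr_cost  <- matrix(0, n, TT)
    tr_util  <- matrix(0, n, TT)
  }

  for (t in seq_len(TT)) {
    alive <- clin <= STATES[["SURVIVOR"]]
    cost <- numeric(n)
    util <- numeric(n)

    # ---- screening at the start of the cycle --------------------------
    fp_event <- bx_event <- rep.int(FALSE, n)
    if (screening_on && due[t]) {
      elig <- alive & !det & clin <= STATES[["STAGE_IV"]]
      attended <- elig & U$att[, t] < st$intake_rate
      dis <- attended & clin >= STATES[["DCIS"]]
      pos <- dis & U$scr[, t] < sens_by_clin[clin]
      hfp <- attended & clin == STATES[["HEALTHY"]] & U$scr[, t] < fp_rate
      bx_event <- pos | (hfp & U$bx[, t] < cfg$screening$p_fp_biopsy)
      newdet <- pos & U$bx[, t] < cfg$biopsy$sensitivity
      fp_event <- hfp
      det[newdet] <- TRUE
      ysd[newdet] <- 0L
      if (any(newdet)) {
        n_screen_det <- n_screen_det + sum(newdet)
        stg <- stage_of(clin[newdet])
        tab <- tabulate(stg, nbins = 5L)
        stage_at_dx <- stage_at_dx + tab
        if (classify_overdx) {
          dcis_idx <- which(newdet & clin == STATES[["DCIS"]])
          for (i in dcis_idx)
            overdx[i] <- classify_overdiagnosis(ages[t], cfg, child_seeds[i])
        }
      }
      cost[attended] <- screen_cost
      cost[bx_event] <- cost[bx_event] + ec$cost_biopsy
      n_screens <- n_screens + sum(attended)
      n_biopsies <- n_biopsies + sum(bx_event)
      n_fp <- n_fp + sum(fp_event)
    }

    # ---- cycle ledger --------------------------------------------------
    y1  <- det & ysd == 0L & clin >= STATES[["DCIS"]] & clin <= STATES[["STAGE_IV"]]
    y25 <- det & ysd >= 1L & ysd <= 4L &
      clin >= STATES[["DCIS"]] & clin <= STATES[["STAGE_IV"]]
    cost[y1]  <- cost[y1]  + tx1[stage_of(clin[y1])]
    cost[y25] <- cost[y25] + tx25[stage_of(clin[y25])]
    if (ec$cost_survivor_annual > 0) {
      sv <- clin == STATES[["SURVIVOR"]]
      cost[sv] <- cost[sv] + ec$cost_survivor_annual
    }

    util[clin == STATES[["HEALTHY"]]] <- u_healthy[t]
    ds <- clin >= STATES[["DCIS"]] & clin <= STATES[["STAGE_IV"]]
    util[ds] <- u_state[stage_of(clin[ds])]
    util[clin == STATES[["SURVIVOR"]]] <-
      if (surv_age_matched) u_healthy[t] else cfg$utils$u_survivor_fixed
    if (cfg$utils$disutil_fp > 0)
      util[fp_event] <- util[fp_event] - cfg$utils$disutil_fp
    if (cfg$utils$disutil_biopsy > 0)
      util[bx_event] <- util[bx_event] - cfg$utils$disutil_biopsy
    util[util < 0] <- 0
    util[!alive] <- 0

    disc_cost <- disc_cost + cost * dfc[t]
    disc_qaly <- disc_qaly + util * dfe[t]
    py_at_risk[t] <- sum(alive & !ever_inv)
    if (trace) { tr_state[, t] <- clin; tr_cost[, t] <- cost; tr_util[, t] <- util }

    # ---- natural-history transition at the end of the cycle -----------
    die_oth <- alive & U$dth[, t] < q_mort[t]
    surv <- alive & !die_oth

    # symptomatic diagnosis of undetected invasive disease
    und_inv <- surv & !det & clin >= STATES[["STAGE_I"]] &
      clin <= STATES[["STAGE_IV"]]
    psym <- c(nh$p_sympt_dx_I, nh$p_sympt_dx_II, nh$p_sympt_dx_III,
              nh$p_sympt_dx_IV)
    p_sy <- numeric(n)
    p_sy[und_inv] <- psym[clin[und_inv] - 2L]
    sy <- und_inv & U$sym[, t] < p_sy
    if (any(sy)) {
      det[sy] <- TRUE
      ysd[sy] <- 0L
      stage_at_dx <- stage_at_dx + tabulate(stage_of(clin[sy]), nbins = 5L)
    }

    # breast-cancer death: detected stage IV within the 5 treatment years,
    # excluding women diagnosed at this very transition (their year-1 risk
    # starts at the next transition)
    riskIV <- surv & det & clin == STATES[["STAGE_IV"]] & !sy & ysd <= 4L
    p_bc <- ifelse(ysd == 0L, mt$p_bc_death_stageIV_y1,
                   mt$p_bc_death_stageIV_y2to5)
    bcd <- riskIV & U$bcd[, t] < p_bc
    n_bc_death <- n_bc_death + sum(bcd)

    # progression / regression / onset for surviving undetected women
    und <- surv & !det & !bcd
    up <- U$prg[, t]
    onset_hit <- und & clin == STATES[["HEALTHY"]] & up < p_onset[t]
    d_reg <- und & clin == STATES[["DCIS"]] & up < nh$p_dcis_regress
    d_pro <- und & clin == STATES[["DCIS"]] & !d_reg &
      up < nh$p_dcis_regress + nh$p_dcis_to_I
    pr1 <- und & clin == STATES[["STAGE_I"]]   & up < nh$p_I_to_II
    pr2 <- und & clin == STATES[["STAGE_II"]]  & up < nh$p_II_to_III
    pr3 <- und & clin == STATES[["STAGE_III"]] & up < nh$p_III_to_IV

    # relapse of treated stage I-III to detected stage IV
    relc <- surv & !bcd & det & !sy & clin >= STATES[["STAGE_I"]] &
      clin <= STATES[["STAGE_III"]] & ysd <= 4L
    p_rel <- numeric(n)
    relc1 <- relc & ysd == 0L
    relc25 <- relc & ysd >= 1L
    p_rel[relc1] <- rel1[clin[relc1] - 2L]
    p_rel[relc25] <- rel25[clin[relc25] - 2L]
    rel <- relc & U$rel[, t] < p_rel

    # apply transitions
    clin[die_oth] <- STATES[["DEAD_OTHER"]]
    clin[bcd] <- STATES[["DEAD_BC"]]
    clin[onset_hit] <- STATES[["DCIS"]]
    clin[d_reg] <- STATES[["HEALTHY"]]
    clin[d_pro] <- STATES[["STAGE_I"]]
    clin[pr1] <- STATES[["STAGE_II"]]
    clin[pr2] <- STATES[["STAGE_III"]]
    clin[pr3] <- STATES[["STAGE_IV"]]
    clin[rel] <- STATES[["STAGE_IV"]]
    ysd[rel] <- 0L

    inc_events[t] <- sum(d_pro & !ever_inv)
    ever_inv[d_pro] <- TRUE

    # advance the post-diagnosis clock; enter survivorship after year 5
    adv <- surv & !bcd & det & !sy & !rel &
      clin >= STATES[["DCIS"]] & clin <= STATES[["STAGE_IV"]]
    ysd[adv] <- ysd[adv] + 1L
    to_surv <- adv & ysd == 5L
    clin[to_surv] <- STATES[["SURVIVOR"]]
  }

  res <- list(
    strategy_id = strategy$id,
    mean_disc_cost = mean(disc_cost),
    mean_disc_qaly = mean(disc_qaly),
    bc_deaths_per_10k = 10000 * n_bc_death / n,
    invasive_incident_per_10k = 10000 * sum(ever_inv) / n,
    overdiagnosed_dcis_per_10k = 10000 * sum(overdx) / n,
    screens_per_woman = n_screens / n,
    biopsies_per_10k = 10000 * n_biopsies / n,
    screen_detected_per_10k = 10000 * n_screen_det / n,
    false_pos_per_10k = 10000 * n_fp / n,
    stage_at_dx = stage_at_dx,
    inc_events = inc_events,
    py_at_risk = py_at_risk,
    n_individuals = n, n_cycles = TT, seed = seed)
  if (trace) res$trace <- list(state = tr_state, cost = tr_cost, util = tr_util)
  class(res) <- "msim_cohort"
  res
}

#' @export
print.msim_cohort <- function(x, ...) {
  cat(sprintf("<%s: n=%d, %d cycles, seed %d>\n", x$strategy_id,
              x$n_individuals, x$n_cycles, x$seed))
  cat(sprintf("  mean discounted cost  %10.2f USD\n", x$mean_disc_cost))
  cat(sprintf("  mean discounted QALYs %10.4f\n", x$mean_disc_qaly))
  cat(sprintf("  per 10,000 women: %.0f BC deaths, %.0f incident invasive, %.0f overdiagnosed DCIS\n",
              x$bc_deaths_per_10k, x$invasive_incident_per_10k,
              x$overdiagnosed_dcis_per_10k))
  invisible(x)
}

#' Summarize several cohort runs into a strategy table
#'
#' @param results a list of `msim_cohort` objects (distinct strategies).
#' @return a data.frame, one row per strategy, sorted by effect ascending:
#'   `strategy`, `cost`, `qaly`, `deaths_per_10k`, `incidence_per_10k`,
#'   `overdx_per_10k`.
#' @export
summarize_cohorts <- function(results) {
  if (length(results) < 1L) stop("need at least one cohort result")
  ids <- vapply(results, function(r) r$strategy_id, character(1L))
  if (anyDuplicated(ids)) stop("duplicate strategy ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  df <- data.frame(
    strategy = ids,
    cost = vapply(results, function(r) r$mean_disc_cost, numeric(1L)),
    qaly = vapply(results, function(r) r$mean_disc_qaly, numeric(1L)),
    deaths_per_10k = vapply(results, function(r) r$bc_deaths_per_10k, numeric(1L)),
    incidence_per_10k = vapply(results, function(r) r$invasive_incident_per_10k, numeric(1L)),
    overdx_per_10k = vapply(results, function(r) r$overdiagnosed_dcis_per_10k, numeric(1L)),
    stringsAsFactors = FALSE)
  df[order(df$qaly), , drop = FALSE]
}

#' Run several strategies under common random numbers
#'
#' Convenience wrapper: runs each strategy with the *same* seed so that
#' every woman's natural-history randomness is shared across strategies.
#'
#' @param cfg an `msim_config`.
#' @param strategies character vector of strategy ids (default: all ten).
#' @param seed integer seed shared by all runs.
#' @inheritParams run_cohort
#' @return a named list of `msim_cohort` objects.
#' @export
run_strategies <- function(cfg, strategies = strategy_registry()$id, seed,
                           n = NULL, classify_overdx = TRUE) {
  n <- as.integer(n %||% cfg$settings$n_individuals)
  TT <- as.integer(cfg$settings$n_cycles)
  set.seed(as.integer(seed))
  U <- draw_uniforms(n, TT)
  out <- lapply(strategies, function(id)
    run_cohort_impl(cfg, screening_strategy(id), seed = as.integer(seed),
                    U = U, n = n, classify_overdx = classify_overdx))
  names(out) <- strategies
  out
}
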