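#' Draw one probabilistic-sensitivity-analysis configuration
#'
#' Substitutes one independent draw from every resolved parameter
#' distribution into a copy of the configuration. Fixed parameters are
#' untouched. Draws are reproducible from `(master seed, draw index)`.
#' Stage-IV screening sensitivity always mirrors the sampled stage-III
#' value (monotone sensitivity in stage), and the single discounting
#' parameter feeds both the cost and effect rates. If a draw makes the
#' DCIS row infeasible (regression + progression > 1) it is redrawn up to
#' `max_redraw` times and then proportionally rescaled; the number of
#' redraws is recorded in `attr(cfg, "psa_redraws")`.
#'
#' @param cfg an `msim_config`.
#' @param seed master seed.
#' @param index draw index (1-based).
#' @param resolved optional pre-resolved distribution list from
#'   `resolve_all_distributions` (a speed-up for repeated calls).
#' @param max_redraw redraw cap for infeasible DCIS rows.
#' @return a validated `msim_config` with sampled parameters.
#' @export
sample_psa_config <- function(cfg, seed, index, resolved = NULL,
                              max_redraw = 100L) {
  dt <- cfg$distributions
  if (is.null(dt) || nrow(dt) == 0L) return(cfg)
  if (is.null(resolved)) resolved <- resolve_all_distributions(dt)
  draw_seed <- (as.numeric(seed) + 7919 * as.numeric(index)) %% 2147483647
  set.seed(as.integer(draw_seed))
  redraws <- 0L
  repeat {
    u <- stats::runif(length(resolved))
    vals <- vapply(seq_along(resolved),
                   function(i) resolved[[i]]$qfun(u[i]), numeric(1L))
    names(vals) <- names(resolved)
    ok <- vals[["nat_hist.p_dcis_to_I"]] + vals[["nat_hist.p_dcis_regress"]] <= 1
    if (ok || redraws >= max_redraw) break
    redraws <- redraws + 1L
  }
  if (vals[["nat_hist.p_dcis_to_I"]] + vals[["nat_hist.p_dcis_regress"]] > 1) {
    s <- vals[["nat_hist.p_dcis_to_I"]] + vals[["nat_hist.p_dcis_regress"]]
    vals[["nat_hist.p_dcis_to_I"]] <- vals[["nat_hist.p_dcis_to_I"]] / s
    vals[["nat_hist.p_dcis_regress"]] <- vals[["nat_hist.p_dcis_regress"]] / s
  }
  # utility weights are bounded above by perfect health
  iu <- grepl("^utils\\.u_state\\.", names(vals))
  vals[iu] <- pmin(vals[iu], 1)
  out <- cfg
  for (p in names(vals)) out <- config_set(out, p, vals[[p]])
  # stage IV sensitivity inherits the sampled stage III operating point
  for (m in names(out$tests))
    out$tests[[m]]$sens_by_stage[["IV"]] <- out$tests[[m]]$sens_by_stage[["III"]]
  attr(out, "psa_redraws") <- redraws
  validate_config(out)
  out
}

#' Run a probabilistic sensitivity analysis
#'
#' For each of `n_draws` parameter draws, samples a configuration with
#' [sample_psa_config()] and runs every strategy on a cohort of
#' `n_individuals` women under common random numbers (all strategies
#' within a draw share one engine seed), recording mean discounted cost
#' and QALYs. Results are identical for a given `(seed, n_draws)`
#' regardless of evaluation order.
#'
#' @param cfg an `msim_config`.
#' @param strategies character vector of strategy ids.
#' @param n_draws number of parameter draws.
#' @param n_individuals cohort size per draw.
#' @param seed master seed.
#' @return an `msim_psa`: data.frame `draws` with columns `draw`,
#'   `strategy`, `cost`, `effect`, plus the run dimensions.
#' @export
run_psa <- function(cfg, strategies = strategy_registry()$id,
                    n_draws = 200L, n_individuals = 2000L, seed = 1L) {
  if (n_draws < 1L) stop("n_draws must be >= 1")
  resolved <- resolve_all_distributions(cfg$distributions)
  rows <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    cfg_d <- sample_psa_config(cfg, seed = seed, index = d,
                               resolved = resolved)
    engine_seed <- (as.numeric(seed) + 104729 * d) %% 2147483647
    res <- run_strategies(cfg_d, strategies, seed = as.integer(engine_seed),
                          n = n_individuals, classify_overdx = FALSE)
    rows[[d]] <- data.frame(
      draw = d, strategy = strategies,
      cost = vapply(res, function(r) r$mean_disc_cost, numeric(1L)),
      effect = vapply(res, function(r) r$mean_disc_qaly, numeric(1L)),
      stringsAsFactors = FALSE)
  }
  out <- list(draws = do.call(rbind, rows), n_draws = n_draws,
              n_individuals = n_individuals, seed = seed,
              strategies = strategies)
  class(out) <- "msim_psa"
  out
}

#' @export
print.msim_psa <- function(x, ...) {
  cat(sprintf("<PSA: %d draws x %d women, %d strategies, seed %d>\n",
              x$n_draws, x$n_individuals, length(x$strategies), x$seed))
  invisible(x)
}

#' Probability each strategy is the cost-effective choice
#'
#' The fraction of PSA draws in which each strategy attains the maximal
#' net monetary benefit at the given willingness to pay; exact ties share
#' the draw equally. Probabilities sum to 1.
#'
#' @param psa an `msim_psa`.
#' @param wtp willingness to pay per QALY, `>= 0`.
#' @return a data.frame `strategy`, `probability`, sorted decreasing.
#' @export
selection_probabilities <- function(psa, wtp) {
  stopifnot(inherits(psa, "msim_psa"), wtp >= 0)
  d <- psa$draws
  if (nrow(d) == 0L) stop("empty PSA")
  d$nmb <- nmb(d$cost, d$effect, wtp)
  score <- numeric(length(psa$strategies))
  names(score) <- psa$strategies
  for (dd in split(d, d$draw)) {
    best <- dd$nmb == max(dd$nmb)
    score[dd$strategy[best]] <- score[dd$strategy[best]] + 1 / sum(best)
  }
  out <- data.frame(strategy = names(score),
                    probability = as.numeric(score) / psa$n_draws,
                    stringsAsFactors = FALSE)
  out[order(-out$probability), , drop = FALSE]
}

#' Cost-effectiveness acceptability frontier
#'
#' For each willingness-to-pay value: the strategy with the highest *mean*
#' net monetary benefit across draws (the frontier strategy) and the
#' probability that this strategy is optimal draw by draw.
#'
#' @param psa an `msim_psa`.
#' @param wtp_grid numeric vector of willingness-to-pay values.
#' @return a data.frame `wtp`, `frontier_strategy`, `probability`.
#' @export
ceaf <- function(psa, wtp_grid) {
  stopifnot(inherits(psa, "msim_psa"), length(wtp_grid) >= 1L)
  out <- lapply(wtp_grid, function(w) {
    d <- psa$draws
    d$nmb <- nmb(d$cost, d$effect, w)
    mean_nmb <- tapply(d$nmb, d$strategy, mean)
    front <- names(mean_nmb)[which.max(mean_nmb)]
    sel <- selection_probabilities(psa, w)
    data.frame(wtp = w, frontier_strategy = front,
               probability = sel$probability[sel$strategy == front],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Default deterministic scenario table
#'
#' The one-way scenarios evaluated by [one_way_scenarios()] when none are
#' supplied: for each headline parameter (concurrent-AI diagnostic
#' accuracy, the discount rate, the probability of biopsy after a false
#' positive, the false-positive disutility, and the per-screen AI cost) an
#' optimistic and a conservative value spanning its credible range.
#'
#' @param cfg an `msim_config` (for the AI accuracy block baselines).
#' @return a data.frame `scenario`, `path`, `value`.
#' @export
default_scenarios <- function(cfg) {
  rbind(
    data.frame(scenario = "ai_sens_dcis_low",  path = "tests.AI_CONCURRENT.sens_by_stage.DCIS", value = 0.36),
    data.frame(scenario = "ai_sens_dcis_high", path = "tests.AI_CONCURRENT.sens_by_stage.DCIS", value = 0.54),
    data.frame(scenario = "ai_sens_I_low",     path = "tests.AI_CONCURRENT.sens_by_stage.I",    value = 0.71),
    data.frame(scenario = "ai_sens_I_high",    path = "tests.AI_CONCURRENT.sens_by_stage.I",    value = 1.00),
    data.frame(scenario = "ai_spec_low",       path = "tests.AI_CONCURRENT.specificity",        value = 0.90),
    data.frame(scenario = "ai_spec_high",      path = "tests.AI_CONCURRENT.specificity",        value = 1.00),
    data.frame(scenario = "discount_low",      path = "econ.discount",          value = 0.04),
    data.frame(scenario = "discount_high",     path = "econ.discount",          value = 0.06),
    data.frame(scenario = "fp_biopsy_low",     path = "screening.p_fp_biopsy",  value = 0.95),
    data.frame(scenario = "fp_biopsy_high",    path = "screening.p_fp_biopsy",  value = 1.00),
    data.frame(scenario = "disutil_fp_low",    path = "utils.disutil_fp",       value = 0.00),
    data.frame(scenario = "disutil_fp_high",   path = "utils.disutil_fp",       value = 0.01),
    data.frame(scenario = "ai_cost_low",       path = "econ.cost_ai_per_screen", value = 0.75),
    data.frame(scenario = "ai_cost_high",      path = "econ.cost_ai_per_screen", value = 3.00))
}

#' One-way deterministic scenario (tornado) analysis
#'
#' Re-runs the strategy comparison varying one parameter at a time, the
#' rest held at base case, under a fixed engine seed (so a scenario that
#' sets a parameter to its base value reproduces the base case exactly).
#' Reports, per scenario, the focal strategy's total discounted cost and
#' QALYs and the headline ICER (focal vs comparator), plus the signed
#' spread against base case used to order tornado bars.
#'
#' @param cfg an `msim_config`.
#' @param scenarios a data.frame `scenario`, `path`, `value`
#'   (default: [default_scenarios()]).
#' @param focal,comparator strategy ids for the headline ICER.
#' @param seed engine seed (common random numbers across scenarios).
#' @param n cohort size per run.
#' @return an `msim_tornado` data.frame: `scenario`, `path`, `value`,
#'   `cost`, `qaly`, `icer`, `icer_spread`.
#' @export
one_way_scenarios <- function(cfg, scenarios = NULL,
                              focal = "sim_mammo_AI_D1",
                              comparator = "sim_mammo_AI_D2",
                              seed = 1L, n = 2000L) {
  if (is.null(scenarios)) scenarios <- default_scenarios(cfg)
  stopifnot(all(c("scenario", "path", "value") %in% names(scenarios)))
  run_pair <- function(cfg2) {
    res <- run_strategies(cfg2, c(comparator, focal), seed = seed, n = n,
                          classify_overdx = FALSE)
    c(cost = res[[focal]]$mean_disc_cost,
      qaly = res[[focal]]$mean_disc_qaly,
      icer = (res[[focal]]$mean_disc_cost - res[[comparator]]$mean_disc_cost) /
             (res[[focal]]$mean_disc_qaly - res[[comparator]]$mean_disc_qaly))
  }
  base <- run_pair(cfg)
  rows <- lapply(seq_len(nrow(scenarios)), function(i) {
    cfg2 <- config_set(cfg, scenarios$path[i], scenarios$value[i])
    validate_config(cfg2)
    v <- run_pair(cfg2)
    data.frame(scenario = scenarios$scenario[i], path = scenarios$path[i],
               value = scenarios$value[i], cost = v[["cost"]],
               qaly = v[["qaly"]], icer = v[["icer"]],
               icer_spread = v[["icer"]] - base[["icer"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "base") <- base
  class(out) <- c("msim_tornado", "data.frame")
  out
}

#' Tornado bar widths per parameter
#'
#' Collapses a scenario table to one row per parameter path with the total
#' ICER swing between its scenarios, sorted widest first.
#'
#' @param tornado an `msim_tornado` from [one_way_scenarios()].
#' @return data.frame `path`, `icer_low`, `icer_high`, `width`.
#' @export
tornado_widths <- function(tornado) {
  sp <- split(as.data.frame(tornado), tornado$path)
  out <- do.call(rbind, lapply(sp, function(d)
    data.frame(path = d$path[1L], icer_low = min(d$icer),
               icer_high = max(d$icer), width = diff(range(d$icer)))))
  rownames(out) <- NULL
  out[order(-out$width), , drop = FALSE]
}

#' Cohort-size convergence of the headline ICER
#'
#' For each cohort size in `n_grid`, re-estimates the headline ICER
#' (focal vs comparator) across `replicates` independent seeds and
#' reports the replicate standard deviation. Monte-Carlo noise should
#' shrink roughly as `n^-1/2`, flattening once the cohort is large
#' enough.
#'
#' @param cfg an `msim_config`.
#' @param n_grid ascending integer vector of cohort sizes.
#' @param replicates number of independent seeds per size (>= 2 for an
#'   SD; a single replicate yields `NA` with a flag).
#' @param seed base seed; replicate seeds are derived from it.
#' @param focal,comparator strategy ids for the headline ICER.
#' @return data.frame `n`, `mean_icer`, `sd_icer`, `flag`.
#' @export
convergence_scan <- function(cfg, n_grid, replicates = 5L, seed = 1L,
                             focal = "sim_mammo_AI_D1",
                             comparator = "sim_noscreening") {
  stopifnot(!is.unsorted(n_grid))
  out <- lapply(n_grid, function(nn) {
    icers <- vapply(seq_len(replicates), function(r) {
      s <- (as.numeric(seed) + 33331 * r + nn) %% 2147483647
      res <- run_strategies(cfg, c(comparator, focal), seed = as.integer(s),
                            n = nn, classify_overdx = FALSE)
      (res[[focal]]$mean_disc_cost - res[[comparator]]$mean_disc_cost) /
        (res[[focal]]$mean_disc_qaly - res[[comparator]]$mean_disc_qaly)
    }, numeric(1L))
    data.frame(n = nn, mean_icer = mean(icers),
               sd_icer = if (replicates >= 2L) stats::sd(icers) else NA_real_,
               flag = if (replicates >= 2L) "" else "sd undefined (1 replicate)")
  })
  do.call(rbind, out)
}
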