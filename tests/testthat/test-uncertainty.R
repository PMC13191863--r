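test_that("PSA configuration draws are reproducible and well-behaved", {
  cfg <- base_cfg()
  a <- sample_psa_config(cfg, seed = 5, index = 3)
  b <- sample_psa_config(cfg, seed = 5, index = 3)
  expect_equal(unclass(a), unclass(b))
  c <- sample_psa_config(cfg, seed = 5, index = 4)
  expect_false(identical(a$nat_hist$p_dcis_to_I, c$nat_hist$p_dcis_to_I))

  # with every distribution degenerate the draw is the baseline itself
  cfg_fixed <- cfg
  cfg_fixed$distributions$kind <- "fixed"
  d <- sample_psa_config(cfg_fixed, seed = 5, index = 1)
  expect_equal(d$nat_hist, cfg$nat_hist)
  expect_equal(d$econ, cfg$econ)
  expect_equal(d$utils, cfg$utils)

  # sampled stage IV sensitivity mirrors stage III; DCIS row stays feasible
  draws <- lapply(1:50, function(i) sample_psa_config(cfg, seed = 7, index = i))
  for (d in draws) {
    for (m in names(d$tests))
      expect_equal(d$tests[[m]]$sens_by_stage[["IV"]],
                   d$tests[[m]]$sens_by_stage[["III"]])
    expect_lte(d$nat_hist$p_dcis_to_I + d$nat_hist$p_dcis_regress, 1)
    expect_equal(d$econ$discount_cost, d$econ$discount_effect)
  }
  # the sampled progression probability is centred on its baseline
  v <- vapply(draws, function(d) d$nat_hist$p_dcis_to_I, numeric(1))
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 0.21), 3 * se)
})

test_that("PSA runs are deterministic and selection probabilities normalize", {
  cfg <- base_cfg()
  ids <- c("sim_noscreening", "sim_mammo_AI_D1", "sim_mammo_D2")
  psa <- run_psa(cfg, ids, n_draws = 6, n_individuals = 400, seed = 2)
  psa2 <- run_psa(cfg, ids, n_draws = 6, n_individuals = 400, seed = 2)
  expect_identical(psa$draws, psa2$draws)
  expect_equal(nrow(psa$draws), 6L * 3L)     # rectangular

  sel <- selection_probabilities(psa, 4500)
  expect_equal(sum(sel$probability), 1)
  expect_true(all(sel$probability >= 0))

  one <- run_psa(cfg, "sim_noscreening", n_draws = 3, n_individuals = 200,
                 seed = 2)
  sel1 <- selection_probabilities(one, 4500)
  expect_equal(sel1$probability, 1)
  expect_error(selection_probabilities(psa, -1))
})

test_that("the acceptability frontier matches a direct argmax recount", {
  cfg <- base_cfg()
  ids <- c("sim_noscreening", "sim_mammo_AI_D1", "sim_mammo_D2")
  psa <- run_psa(cfg, ids, n_draws = 8, n_individuals = 300, seed = 6)
  grid <- c(0, 2000, 4500, 20000)
  cf <- ceaf(psa, grid)
  expect_equal(nrow(cf), length(grid))

  # at zero willingness to pay the cheapest strategy is the frontier
  d0 <- psa$draws
  mean_cost <- tapply(d0$cost, d0$strategy, mean)
  expect_identical(cf$frontier_strategy[1],
                   names(mean_cost)[which.min(mean_cost)])

  # oracle recount: frontier probability equals the draw-by-draw NMB tally
  for (i in seq_along(grid)) {
    d <- psa$draws
    d$nmb <- grid[i] * d$effect - d$cost
    wins <- vapply(split(d, d$draw), function(dd) {
      best <- dd$nmb == max(dd$nmb)
      if (dd$strategy[best][1] == cf$frontier_strategy[i])
        1 / sum(best) else sum(best[dd$strategy == cf$frontier_strategy[i]]) / sum(best)
    }, numeric(1))
    expect_equal(cf$probability[i], mean(wins))
  }
})

test_that("one-way scenarios reproduce base case at base values and order discounting", {
  cfg <- base_cfg()
  null_scen <- data.frame(scenario = "null",
                          path = "econ.cost_ai_per_screen",
                          value = cfg$econ$cost_ai_per_screen)
  tor <- one_way_scenarios(cfg, null_scen, seed = 3, n = 600)
  expect_equal(tor$icer_spread, 0)
  expect_equal(unname(tor$cost), unname(attr(tor, "base")[["cost"]]))

  # a higher discount rate strictly lowers every strategy's QALY total
  lo <- run_strategies(cfg, c("sim_noscreening", "sim_mammo_AI_D1"),
                       seed = 4, n = 800, classify_overdx = FALSE)
  cfg_hi <- cfg
  cfg_hi$econ$discount_effect <- 0.08
  hi <- run_strategies(cfg_hi, c("sim_noscreening", "sim_mammo_AI_D1"),
                       seed = 4, n = 800, classify_overdx = FALSE)
  for (id in names(lo))
    expect_lt(hi[[id]]$mean_disc_qaly, lo[[id]]$mean_disc_qaly)

  expect_error(one_way_scenarios(cfg, data.frame(
    scenario = "bad", path = "nowhere.at.all", value = 1), n = 100),
    "unknown parameter path")

  # tornado widths collapse scenarios per parameter, widest first
  scen <- default_scenarios(cfg)
  scen <- scen[scen$path %in% c("econ.discount", "econ.cost_ai_per_screen"), ]
  tor2 <- one_way_scenarios(cfg, scen, seed = 3, n = 600)
  w <- tornado_widths(tor2)
  expect_equal(nrow(w), 2L)
  expect_true(!is.unsorted(rev(w$width)))
})

test_that("ICER dispersion shrinks with cohort size", {
  cfg <- base_cfg()
  conv <- convergence_scan(cfg, n_grid = c(150, 3000), replicates = 4,
                           seed = 8)
  expect_equal(nrow(conv), 2L)
  expect_true(all(is.finite(conv$sd_icer)))
  expect_gt(conv$sd_icer[1], conv$sd_icer[2])

  single <- convergence_scan(cfg, n_grid = 100, replicates = 1, seed = 8)
  expect_true(is.na(single$sd_icer))
  expect_match(single$flag, "undefined")
})
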