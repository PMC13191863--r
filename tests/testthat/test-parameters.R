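test_that("packaged defaults reproduce the published parameter set", {
  cfg <- default_config()
  nh <- cfg$nat_hist
  expect_equal(nh$p_dcis_to_I, 0.21)
  expect_equal(nh$p_I_to_II, 0.24)
  expect_equal(nh$p_II_to_III, 0.29)
  expect_equal(nh$p_III_to_IV, 0.50)
  expect_equal(nh$p_dcis_regress, 0.25)
  expect_equal(c(nh$p_sympt_dx_I, nh$p_sympt_dx_II, nh$p_sympt_dx_III),
               c(0.025, 0.22, 0.55))
  expect_equal(nh$onset_by_age$values,
               c(0.0004854, 0.0005101, 0.0017720, 0.0017103,
                 0.0016956, 0.0025666, 0.0017920, 0.0006337))
  expect_equal(cfg$mortality$allcause_by_age$values,
               c(0.001061, 0.001607, 0.002597, 0.004357,
                 0.007751, 0.012888, 0.022476, 0.043894))
  expect_equal(cfg$mortality$p_bc_death_stageIV_y1, 0.742725)
  expect_equal(cfg$mortality$p_bc_death_stageIV_y2to5, 0.2642997)
  expect_equal(unname(cfg$mortality$relapse_y1),
               c(0.04310727, 0.2099324, 0.524831))
  expect_equal(unname(cfg$mortality$relapse_y2to5),
               c(0.1193797, 0.1524264, 0.06317258))
  expect_equal(unname(cfg$tests$MAMMO$sens_by_stage),
               c(0.40, 0.77, 0.94, 0.99, 0.99))
  expect_equal(cfg$tests$MAMMO$specificity, 0.96)
  expect_equal(unname(cfg$tests$AI_CONCURRENT$sens_by_stage),
               c(0.45, 0.89, 0.99, 0.99, 0.99))
  expect_equal(cfg$tests$AI_CONCURRENT$specificity, 0.93)
  expect_equal(unname(cfg$tests$AI_TRIAGE$sens_by_stage),
               c(0.17, 0.63, 0.93, 0.99, 0.99))
  expect_equal(cfg$tests$AI_TRIAGE$specificity, 0.966)
  expect_equal(unname(cfg$econ$tx_cost_y1), c(409, 698, 2406, 3203, 4136))
  expect_equal(unname(cfg$econ$tx_cost_y2to5), c(65, 111, 478, 1008, 3178))
  expect_equal(cfg$econ$cost_mammogram, 7.71)
  expect_equal(cfg$econ$cost_biopsy, 21.67)
  expect_equal(cfg$econ$cost_coordination, 0.68)
  expect_equal(cfg$utils$u_healthy_by_age$values, c(0.75, 0.71, 0.68, 0.65))
  expect_equal(unname(cfg$utils$u_state), c(0.61, 0.63, 0.63, 0.62, 0.55))
  expect_equal(unname(cfg$init_stage_distribution), c(0.11, 0.51, 0.31, 0.07))
  expect_equal(cfg$settings$n_individuals, 10000L)
  expect_equal(cfg$settings$n_cycles, 40L)
  expect_equal(cfg$settings$intake_rate, 0.8)
  expect_equal(cfg$settings$wtp, 4500)
})

test_that("load_config merges overrides and enumerates every violation", {
  # empty override file returns the packaged baseline
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", tmp)
  expect_equal(load_config(tmp)$nat_hist$p_dcis_to_I, 0.21)

  # packaged file round-trips exactly
  pkg_yaml <- system.file("extdata", "params_baseline.yaml",
                          package = "mammosim")
  expect_true(nzchar(pkg_yaml))
  cfg2 <- load_config(pkg_yaml)
  expect_equal(unclass(cfg2), unclass(default_config()), tolerance = 1e-12)

  # a written config reloads identically (round trip through yaml)
  cfg <- default_config()
  cfg$settings$intake_rate <- 0.65
  out <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, out)
  expect_equal(unclass(load_config(out)), unclass(cfg), tolerance = 1e-12)

  # overrides merge by name
  cfg3 <- load_config(overrides = list(
    nat_hist = list(p_I_to_II = 0.3),
    econ = list(tx_cost_y1 = list(II = 2500))))
  expect_equal(cfg3$nat_hist$p_I_to_II, 0.3)
  expect_equal(cfg3$econ$tx_cost_y1[["II"]], 2500)
  expect_equal(cfg3$econ$tx_cost_y1[["I"]], 698)

  # all violations reported at once, naming the fields
  err <- tryCatch(
    load_config(overrides = list(nat_hist = list(p_III_to_IV = 1.5),
                                 settings = list(n_individuals = 0))),
    error = conditionMessage)
  expect_match(err, "p_III_to_IV")
  expect_match(err, "n_individuals")

  expect_error(load_config("no/such/file.yaml"), "not found")
  expect_error(age_band_table(c(40, 46), c(44, 49), c(0.1, 0.2)),
               "contiguous")
})

test_that("resolved distributions match baselines in mean and range mass", {
  d <- resolve_distribution("beta", 0.21, 0.16, 0.29)
  set.seed(1)
  x <- d$qfun(runif(1e5))
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 0.21), 3 * se)

  f <- resolve_distribution("fixed", 7.71)
  expect_identical(f$qfun(runif(10)), rep(7.71, 10))

  # a degenerate log-normal (baseline 0) is coerced to uniform on the range
  u <- resolve_distribution("lognormal", 0.00, 0.00, 0.01)
  expect_identical(u$kind, "uniform")
  expect_true(u$coerced)
  expect_true(all(u$qfun(runif(1000)) <= 0.01))

  # infeasible and out-of-family specifications are rejected
  expect_error(resolve_distribution("beta", 0.5, 0.6, 0.9), "infeasible")
  expect_error(resolve_distribution("beta", 1.4, 1.2, 1.5), "outside")

  # every packaged non-fixed, non-coerced spec: mean within 3 Monte-Carlo
  # standard errors of baseline. The >= 90%-mass-in-range check only makes
  # sense where the printed range is roughly a central interval around the
  # baseline: with the mean pinned to the baseline, a range whose arms are
  # badly lopsided (one arm > 1.8x the other, e.g. the stage II utility
  # 0.63 with range [0.63, 0.64] or the biopsy cost 21.67 with range
  # [1.66, 28.68]) cannot hold 95% of any such distribution's mass.
  dt <- default_config()$distributions
  set.seed(42)
  p <- runif(1e4)
  for (i in seq_len(nrow(dt))) {
    d <- resolve_distribution(dt[i, ])
    if (d$kind == "fixed" || d$coerced) next
    x <- d$qfun(p)
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - dt$baseline[i]), max(3 * se, 1e-9),
              label = dt$path[i])
    arms <- c(dt$baseline[i] - dt$low[i], dt$up[i] - dt$baseline[i])
    if (min(arms) > 0 && max(arms) / min(arms) <= 1.8)
      expect_gte(mean(x >= dt$low[i] & x <= dt$up[i]), 0.90)
  }
})

test_that("age band lookup clamps above the last band and rejects below", {
  tab <- age_band_table(c(40, 45), c(44, 49), c(0.1, 0.2))
  expect_equal(ab_lookup(tab, c(40, 44, 45, 49, 60)),
               c(0.1, 0.1, 0.2, 0.2, 0.2))
  expect_error(ab_lookup(tab, 39), "below")
})
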