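test_that("transition rows reproduce hand-computed event trees", {
  cfg <- base_cfg()

  # absorbing death states
  for (s in c("DEAD_BC", "DEAD_OTHER")) {
    row <- transition_row(s, FALSE, 0L, 60L, cfg)
    expect_equal(nrow(row), 1L)
    expect_equal(row$prob, 1)
    expect_equal(row$clinical, STATES[[s]])
  }

  # undetected DCIS at age 50: other-cause death first, then the
  # regression/progression split conditional on survival
  row <- transition_row("DCIS", FALSE, 0L, 50L, cfg)
  q <- 0.002597
  get <- function(row, clin, det = FALSE)
    sum(row$prob[row$clinical == STATES[[clin]] & row$detected == det])
  expect_equal(get(row, "DEAD_OTHER"), q)
  expect_equal(get(row, "HEALTHY"), (1 - q) * 0.25)
  expect_equal(get(row, "STAGE_I"), (1 - q) * 0.21)
  expect_equal(get(row, "DCIS"), (1 - q) * 0.54)

  # detected stage IV in the diagnosis year at age 60
  row <- transition_row("STAGE_IV", TRUE, 0L, 60L, cfg)
  expect_equal(get(row, "DEAD_OTHER"), 0.007751)
  expect_equal(get(row, "DEAD_BC"), (1 - 0.007751) * 0.742725)

  # detected stage II in year 3 relapses at the late relapse rate
  row <- transition_row("STAGE_II", TRUE, 2L, 55L, cfg)
  q <- 0.004357
  expect_equal(get(row, "STAGE_IV", det = TRUE), (1 - q) * 0.1524264)

  # year 5 of treatment ends in survivorship
  row <- transition_row("STAGE_I", TRUE, 4L, 58L, cfg)
  expect_equal(get(row, "SURVIVOR", det = TRUE),
               (1 - 0.004357) * (1 - 0.1193797))
})

test_that("every reachable transition row is a probability distribution", {
  cfg <- base_cfg()
  combos <- expand.grid(
    clinical = names(STATES), detected = c(FALSE, TRUE),
    ysd = 0:5, age = c(40L, 52L, 67L, 79L), stringsAsFactors = FALSE)
  # drop structurally impossible combinations
  keep <- !(combos$detected & combos$clinical == "HEALTHY") &
    !(!combos$detected & combos$clinical == "SURVIVOR")
  combos <- combos[keep, ]
  for (i in seq_len(nrow(combos))) {
    row <- transition_row(combos$clinical[i], combos$detected[i],
                          combos$ysd[i], combos$age[i], cfg)
    expect_true(all(row$prob >= 0))
    expect_equal(sum(row$prob), 1, tolerance = 1e-12)
    # breast-cancer death is reachable only from detected stage IV in its
    # five treatment years
    if (any(row$clinical == STATES[["DEAD_BC"]] & row$prob > 0) &&
        combos$clinical[i] != "DEAD_BC") {
      expect_identical(combos$clinical[i], "STAGE_IV")
      expect_true(combos$detected[i])
      expect_lte(combos$ysd[i], 4L)
    }
  }
})

test_that("sample_transition is the inverse-CDF draw over the row order", {
  cfg <- base_cfg()
  row <- transition_row("DEAD_BC", FALSE, 0L, 60L, cfg)
  expect_equal(sample_transition(row, 0.73)$clinical, STATES[["DEAD_BC"]])

  row <- transition_row("DCIS", FALSE, 0L, 50L, cfg)
  # u = 0 picks the first outcome in the documented ordering (death)
  expect_equal(sample_transition(row, 0)$clinical, STATES[["DEAD_OTHER"]])
  # u just below each cumulative boundary picks the matching outcome
  cum <- cumsum(row$prob)
  for (k in seq_len(nrow(row)))
    expect_equal(sample_transition(row, cum[k] - 1e-9)$clinical,
                 row$clinical[k])

  # empirical frequencies match the row probabilities (multinomial, 4 SE)
  set.seed(7)
  u <- runif(2e5)
  draws <- findInterval(u, cum, left.open = TRUE) + 1L
  for (k in seq_len(nrow(row))) {
    p_hat <- mean(draws == k)
    se <- sqrt(row$prob[k] * (1 - row$prob[k]) / length(u))
    expect_lt(abs(p_hat - row$prob[k]), 4 * se + 1e-12)
  }
})

test_that("overdiagnosis classification matches its closed-form limits", {
  cfg <- base_cfg()

  cfg1 <- cfg
  cfg1$nat_hist$p_dcis_regress <- 1
  cfg1$nat_hist$p_dcis_to_I <- 0
  expect_true(all(vapply(1:25, function(s)
    classify_overdiagnosis(50L, cfg1, s), logical(1L))))

  cfg2 <- inert_cfg()              # no background mortality
  cfg2$nat_hist$p_dcis_regress <- 0
  cfg2$nat_hist$p_dcis_to_I <- 1
  expect_false(any(vapply(1:25, function(s)
    classify_overdiagnosis(50L, cfg2, s), logical(1L))))

  # without mortality the overdiagnosis fraction is the two-absorbing-state
  # race probability p_reg / (p_reg + p_prog) = 0.25 / 0.46
  cfg3 <- inert_cfg()
  frac0 <- mean(vapply(1:4000, function(s)
    classify_overdiagnosis(45L, cfg3, s), logical(1L)))
  p_closed <- 0.25 / 0.46
  se <- sqrt(p_closed * (1 - p_closed) / 4000)
  expect_lt(abs(frac0 - p_closed), 4 * se)

  # background mortality adds death-before-invasion to the overdiagnosis
  # side of the race, so the fraction can only grow
  frac_m <- mean(vapply(1:4000, function(s)
    classify_overdiagnosis(45L, base_cfg(), s), logical(1L)))
  expect_gt(frac_m, frac0 - 2 * se)
})

test_that("raising late-stage progression cannot reduce cancer deaths", {
  cfg <- base_cfg()
  lo <- run_cohort(cfg, "sim_noscreening", seed = 5, n = 4000,
                   classify_overdx = FALSE)
  cfg$nat_hist$p_III_to_IV <- 0.9
  hi <- run_cohort(cfg, "sim_noscreening", seed = 5, n = 4000,
                   classify_overdx = FALSE)
  expect_gte(hi$bc_deaths_per_10k, lo$bc_deaths_per_10k)
})
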