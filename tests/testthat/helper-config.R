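# shared fixtures: small/degenerate configurations built in code

base_cfg <- function() default_config()

# a cohort that cannot get sick or die: isolates screening mechanics
inert_cfg <- function(intake = 1) {
  cfg <- default_config()
  zero <- cfg$nat_hist$onset_by_age
  zero$values[] <- 0
  cfg$nat_hist$onset_by_age <- zero
  m <- cfg$mortality$allcause_by_age
  m$values[] <- 0
  cfg$mortality$allcause_by_age <- m
  cfg$settings$intake_rate <- intake
  cfg
}

# frontier statuses as published for the ten-strategy comparison, used as a
# worked example of the dominance algorithm (costs/effects per woman)
published_cea_rows <- function() {
  data.frame(
    strategy = c("sim_noscreening", "sim_mammo_D3", "sim_mammo_AIR_D3",
                 "sim_mammo_AI_D3", "sim_mammo_D2", "sim_mammo_AIR_D2",
                 "sim_mammo_AI_D2", "sim_mammo_AIR_D1", "sim_mammo_D1",
                 "sim_mammo_AI_D1"),
    cost = c(64.41, 110.92, 112.28, 115.91, 143.57, 145.97, 150.93,
             238.74, 240.51, 253.03),
    effect = c(12.3577, 12.3842, 12.3717, 12.3962, 12.4110, 12.3952,
               12.4191, 12.4172, 12.4392, 12.4442),
    stringsAsFactors = FALSE)
}

# independent frontier oracle: a strategy is non-dominated iff it attains
# the maximal net monetary benefit at some willingness to pay >= 0
# (lambda sweep over slope breakpoints); strict dominance is checked
# pairwise; everything else is extended-dominated.
oracle_frontier_status <- function(cost, effect) {
  n <- length(cost)
  D <- vapply(seq_len(n), function(i)
    any(cost <= cost[i] & effect >= effect[i] &
          (cost < cost[i] | effect > effect[i])), logical(1L))
  de <- outer(effect, effect, "-")
  dc <- outer(cost, cost, "-")
  slopes <- dc[de != 0] / de[de != 0]
  lams <- sort(unique(slopes[is.finite(slopes) & slopes > 0]))
  grid <- c(0, if (length(lams)) (c(0, lams) + c(lams, max(lams) * 2 + 1)) / 2,
            if (length(lams)) max(lams) * 2 + 1 else 1)
  ND <- rep(FALSE, n)
  for (l in grid) {
    v <- l * effect - cost
    ND[v == max(v)] <- TRUE
  }
  ifelse(D, "D", ifelse(ND, "ND", "ED"))
}
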