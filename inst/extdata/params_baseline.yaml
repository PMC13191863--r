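nat_hist:
  onset_by_age:
    low:
    - 40
    - 45
    - 50
    - 55
    - 60
    - 65
    - 70
    - 75
    high:
    - 44
    - 49
    - 54
    - 59
    - 64
    - 69
    - 74
    - 79
    values:
    - 0.0004854
    - 0.0005101
    - 0.001772
    - 0.0017103
    - 0.0016956
    - 0.0025666
    - 0.001792
    - 0.0006337
  p_dcis_to_I: 0.21
  p_I_to_II: 0.24
  p_II_to_III: 0.29
  p_III_to_IV: 0.5
  p_dcis_regress: 0.25
  p_sympt_dx_I: 0.025
  p_sympt_dx_II: 0.22
  p_sympt_dx_III: 0.55
  p_sympt_dx_IV: 1.0
mortality:
  allcause_by_age:
    low:
    - 40
    - 45
    - 50
    - 55
    - 60
    - 65
    - 70
    - 75
    high:
    - 44
    - 49
    - 54
    - 59
    - 64
    - 69
    - 74
    - 79
    values:
    - 0.001061
    - 0.001607
    - 0.002597
    - 0.004357
    - 0.007751
    - 0.012888
    - 0.022476
    - 0.043894
  p_bc_death_stageIV_y1: 0.742725
  p_bc_death_stageIV_y2to5: 0.2642997
  relapse_y1:
    I: 0.04310727
    II: 0.2099324
    III: 0.524831
  relapse_y2to5:
    I: 0.1193797
    II: 0.1524264
    III: 0.06317258
tests:
  MAMMO:
    sens_by_stage:
      DCIS: 0.4
      I: 0.77
      II: 0.94
      III: 0.99
      IV: 0.99
    specificity: 0.96
  AI_CONCURRENT:
    sens_by_stage:
      DCIS: 0.45
      I: 0.89
      II: 0.99
      III: 0.99
      IV: 0.99
    specificity: 0.93
  AI_TRIAGE:
    sens_by_stage:
      DCIS: 0.17
      I: 0.63
      II: 0.93
      III: 0.99
      IV: 0.99
    specificity: 0.966
biopsy:
  sensitivity: 1.0
  specificity: 1.0
screening:
  p_fp_biopsy: 1.0
econ:
  cost_mammogram: 7.71
  cost_biopsy: 21.670000000000002
  cost_coordination: 0.68
  cost_ai_per_screen: 1.5
  tx_cost_y1:
    DCIS: 409.0
    I: 698.0
    II: 2406.0
    III: 3203.0
    IV: 4136.0
  tx_cost_y2to5:
    DCIS: 65.0
    I: 111.0
    II: 478.0
    III: 1008.0
    IV: 3178.0
  cost_survivor_annual: 0.0
  discount_cost: 0.05
  discount_effect: 0.05
  discount_first_cycle: no
utils:
  u_healthy_by_age:
    low:
    - 40
    - 50
    - 60
    - 70
    high:
    - 49
    - 59
    - 69
    - 90
    values:
    - 0.75
    - 0.71
    - 0.68
    - 0.65
  u_state:
    DCIS: 0.61
    I: 0.63
    II: 0.63
    III: 0.62
    IV: 0.55
  u_survivor_policy: age_matched_healthy
  u_survivor_fixed: 0.75
  disutil_fp: 0.0
  disutil_biopsy: 0.0
settings:
  n_individuals: 10000
  n_cycles: 40
  start_age: 40
  screen_stop_age: 75
  intake_rate: 0.8
  wtp: 4500.0
  seed_prevalent_disease: no
  prevalent_fraction: 0.0
  master_seed: 1
init_stage_distribution:
  I: 0.11
  II: 0.51
  III: 0.31
  IV: 0.07
incidence_targets:
  low:
  - 40
  - 45
  - 50
  - 55
  - 60
  - 65
  - 70
  - 75
  high:
  - 44
  - 49
  - 54
  - 59
  - 64
  - 69
  - 74
  - 79
  values:
  - 0.0004854
  - 0.0005101
  - 0.001772
  - 0.0017103
  - 0.0016956
  - 0.0025666
  - 0.001792
  - 0.0006337
distributions:
  path:
  - nat_hist.p_dcis_to_I
  - nat_hist.p_I_to_II
  - nat_hist.p_II_to_III
  - nat_hist.p_III_to_IV
  - nat_hist.p_dcis_regress
  - nat_hist.p_sympt_dx_I
  - nat_hist.p_sympt_dx_II
  - nat_hist.p_sympt_dx_III
  - screening.p_fp_biopsy
  - tests.MAMMO.sens_by_stage.DCIS
  - tests.MAMMO.sens_by_stage.I
  - tests.MAMMO.sens_by_stage.II
  - tests.MAMMO.sens_by_stage.III
  - tests.MAMMO.specificity
  - tests.AI_CONCURRENT.sens_by_stage.DCIS
  - tests.AI_CONCURRENT.sens_by_stage.I
  - tests.AI_CONCURRENT.sens_by_stage.II
  - tests.AI_CONCURRENT.sens_by_stage.III
  - tests.AI_CONCURRENT.specificity
  - tests.AI_TRIAGE.sens_by_stage.DCIS
  - tests.AI_TRIAGE.sens_by_stage.I
  - tests.AI_TRIAGE.sens_by_stage.II
  - tests.AI_TRIAGE.sens_by_stage.III
  - tests.AI_TRIAGE.specificity
  - biopsy.sensitivity
  - biopsy.specificity
  - utils.u_state.DCIS
  - utils.u_state.I
  - utils.u_state.II
  - utils.u_state.III
  - utils.u_state.IV
  - utils.disutil_fp
  - utils.disutil_biopsy
  - econ.discount
  - econ.cost_mammogram
  - econ.cost_biopsy
  - econ.cost_coordination
  - econ.tx_cost_y1.DCIS
  - econ.tx_cost_y1.I
  - econ.tx_cost_y1.II
  - econ.tx_cost_y1.III
  - econ.tx_cost_y1.IV
  - econ.tx_cost_y2to5.DCIS
  - econ.tx_cost_y2to5.I
  - econ.tx_cost_y2to5.II
  - econ.tx_cost_y2to5.III
  - econ.tx_cost_y2to5.IV
  kind:
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - beta
  - lognormal
  - lognormal
  - lognormal
  - lognormal
  - lognormal
  - lognormal
  - lognormal
  - beta
  - gamma
  - gamma
  - gamma
  - gamma
  - gamma
  - gamma
  - gamma
  - gamma
  - gamma
  - gamma
  - gamma
  - gamma
  - gamma
  baseline:
  - 0.21
  - 0.24
  - 0.29
  - 0.5
  - 0.25
  - 0.025
  - 0.22
  - 0.55
  - 1.0
  - 0.4
  - 0.77
  - 0.94
  - 0.99
  - 0.96
  - 0.45
  - 0.89
  - 0.99
  - 0.99
  - 0.93
  - 0.17
  - 0.63
  - 0.93
  - 0.99
  - 0.966
  - 1.0
  - 1.0
  - 0.61
  - 0.63
  - 0.63
  - 0.62
  - 0.55
  - 0.0
  - 0.0
  - 0.05
  - 7.71
  - 21.670000000000002
  - 0.68
  - 409.0
  - 698.0
  - 2406.0
  - 3203.0
  - 4136.0
  - 65.0
  - 111.0
  - 478.0
  - 1008.0
  - 3178.0
  low:
  - 0.16
  - 0.19
  - 0.23
  - 0.4
  - 0.2
  - 0.02
  - 0.18
  - 0.44
  - 0.95
  - 0.38
  - 0.74
  - 0.9
  - 0.95
  - 0.95
  - 0.36
  - 0.71
  - 0.95
  - 0.95
  - 0.9
  - 0.13
  - 0.5
  - 0.74
  - 0.95
  - 0.95
  - 0.95
  - 0.95
  - 0.52
  - 0.62
  - 0.63
  - 0.61
  - 0.51
  - 0.0
  - 0.0
  - 0.04
  - 2.14
  - 1.66
  - 0.55
  - 327.0
  - 559.0
  - 1925.0
  - 2562.0
  - 3309.0
  - 52.0
  - 89.0
  - 383.0
  - 807.0
  - 2542.0
  up:
  - 0.29
  - 0.29
  - 0.35
  - 0.6
  - 0.3
  - 0.03
  - 0.26
  - 0.66
  - 1.0
  - 0.42
  - 0.82
  - 1.0
  - 1.0
  - 0.97
  - 0.54
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 0.2
  - 0.75
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 0.7
  - 0.65
  - 0.64
  - 0.64
  - 0.6
  - 0.01
  - 0.01
  - 0.06
  - 14.98
  - 28.68
  - 0.82
  - 491.0
  - 838.0
  - 2887.0
  - 3844.0
  - 4963.0
  - 78.0
  - 133.0
  - 574.0
  - 1210.0
  - 3814.0
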