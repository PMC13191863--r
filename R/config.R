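#' Packaged baseline model configuration
#'
#' Builds the complete baseline parameter set of the model: annual natural
#' history transition probabilities, relapse and breast-cancer mortality
#' rates, age-specific all-cause mortality, stage-specific test performance
#' for three reading modalities (radiologist-only mammography, concurrent
#' AI + radiologist reading, AI triage with radiologist confirmation),
#' treatment costs in year 1 and years 2-5 after diagnosis, utility weights,
#' discount rates, and cohort simulation settings. Each parameter that is
#' varied in probabilistic sensitivity analysis carries a distribution
#' specification (family, baseline, 95% range).
#'
#' The age-specific onset table (`nat_hist$onset_by_age`) holds the
#' calibrated annual probability that a healthy woman develops ductal
#' carcinoma in situ (DCIS); the same schedule is packaged under
#' `incidence_targets` so the calibration machinery has a printed target
#' set to exercise. The per-screen AI cost (`econ$cost_ai_per_screen`,
#' default 1.50 USD) is a placeholder: no tariff exists for AI reading and
#' the value should be replaced with a local estimate; it is a first-class
#' configuration field and a deterministic sensitivity-analysis parameter.
#'
#' @return a validated `msim_config` object (a nested named list).
#' @seealso [load_config()] to override fields from a YAML/JSON file,
#'   [validate_config()] for the validation rules.
#' @export
default_config <- function() {
  bands5 <- function(values)
    age_band_table(seq(40L, 75L, by = 5L), seq(44L, 79L, by = 5L), values)

  onset <- bands5(c(0.0004854, 0.0005101, 0.0017720, 0.0017103,
                    0.0016956, 0.0025666, 0.0017920, 0.0006337))
  allcause <- bands5(c(0.001061, 0.001607, 0.002597, 0.004357,
                       0.007751, 0.012888, 0.022476, 0.043894))
  u_healthy <- age_band_table(c(40L, 50L, 60L, 70L), c(49L, 59L, 69L, 90L),
                              c(0.75, 0.71, 0.68, 0.65))

  tests <- list(
    MAMMO = list(
      sens_by_stage = c(DCIS = 0.40, I = 0.77, II = 0.94, III = 0.99, IV = 0.99),
      specificity   = 0.96),
    AI_CONCURRENT = list(
      sens_by_stage = c(DCIS = 0.45, I = 0.89, II = 0.99, III = 0.99, IV = 0.99),
      specificity   = 0.93),
    AI_TRIAGE = list(
      sens_by_stage = c(DCIS = 0.17, I = 0.63, II = 0.93, III = 0.99, IV = 0.99),
      specificity   = 0.966))

  cfg <- list(
    nat_hist = list(
      onset_by_age   = onset,
      p_dcis_to_I    = 0.21,
      p_I_to_II      = 0.24,
      p_II_to_III    = 0.29,
      p_III_to_IV    = 0.50,
      p_dcis_regress = 0.25,
      p_sympt_dx_I   = 0.025,
      p_sympt_dx_II  = 0.22,
      p_sympt_dx_III = 0.55,
      p_sympt_dx_IV  = 1.0),
    mortality = list(
      allcause_by_age       = allcause,
      p_bc_death_stageIV_y1    = 0.742725,
      p_bc_death_stageIV_y2to5 = 0.2642997,
      relapse_y1    = c(I = 0.04310727, II = 0.2099324,  III = 0.524831),
      relapse_y2to5 = c(I = 0.1193797,  II = 0.1524264,  III = 0.06317258)),
    tests = tests,
    biopsy = list(sensitivity = 1.0, specificity = 1.0),
    screening = list(p_fp_biopsy = 1.0),
    econ = list(
      cost_mammogram     = 7.71,
      cost_biopsy        = 21.67,
      cost_coordination  = 0.68,
      cost_ai_per_screen = 1.50,   # placeholder: no published AI tariff
      tx_cost_y1    = c(DCIS = 409, I = 698,  II = 2406, III = 3203, IV = 4136),
      tx_cost_y2to5 = c(DCIS = 65,  I = 111,  II = 478,  III = 1008, IV = 3178),
      cost_survivor_annual = 0,
      discount_cost   = 0.05,
      discount_effect = 0.05,
      discount_first_cycle = FALSE),
    utils = list(
      u_healthy_by_age = u_healthy,
      u_state = c(DCIS = 0.61, I = 0.63, II = 0.63, III = 0.62, IV = 0.55),
      u_survivor_policy = "age_matched_healthy",
      u_survivor_fixed  = 0.75,
      disutil_fp     = 0.0,
      disutil_biopsy = 0.0),
    settings = list(
      n_individuals   = 10000L,
      n_cycles        = 40L,
      start_age       = 40L,
      screen_stop_age = 75L,
      intake_rate     = 0.8,
      wtp             = 4500,
      seed_prevalent_disease = FALSE,
      prevalent_fraction = 0,
      master_seed     = 1L),
    init_stage_distribution = c(I = 0.11, II = 0.51, III = 0.31, IV = 0.07),
    incidence_targets = onset,
    distributions = default_distributions()
  )
  class(cfg) <- "msim_config"
  validate_config(cfg)
  cfg
}

# Distribution specifications for every parameter varied in PSA.
# `low`/`up` are read as a central 95% interval.
default_distributions <- function() {
  spec <- function(path, kind, baseline, low, up)
    data.frame(path = path, kind = kind, baseline = baseline,
               low = low, up = up, stringsAsFactors = FALSE)
  rbind(
    spec("nat_hist.p_dcis_to_I",    "beta", 0.21,  0.16, 0.29),
    spec("nat_hist.p_I_to_II",      "beta", 0.24,  0.19, 0.29),
    spec("nat_hist.p_II_to_III",    "beta", 0.29,  0.23, 0.35),
    spec("nat_hist.p_III_to_IV",    "beta", 0.50,  0.40, 0.60),
    spec("nat_hist.p_dcis_regress", "beta", 0.25,  0.20, 0.30),
    spec("nat_hist.p_sympt_dx_I",   "beta", 0.025, 0.02, 0.03),
    spec("nat_hist.p_sympt_dx_II",  "beta", 0.22,  0.18, 0.26),
    spec("nat_hist.p_sympt_dx_III", "beta", 0.55,  0.44, 0.66),
    spec("screening.p_fp_biopsy",   "beta", 1.00,  0.95, 1.00),
    spec("tests.MAMMO.sens_by_stage.DCIS", "beta", 0.40, 0.38, 0.42),
    spec("tests.MAMMO.sens_by_stage.I",    "beta", 0.77, 0.74, 0.82),
    spec("tests.MAMMO.sens_by_stage.II",   "beta", 0.94, 0.90, 1.00),
    spec("tests.MAMMO.sens_by_stage.III",  "beta", 0.99, 0.95, 1.00),
    spec("tests.MAMMO.specificity",        "beta", 0.96, 0.95, 0.97),
    spec("tests.AI_CONCURRENT.sens_by_stage.DCIS", "beta", 0.45, 0.36, 0.54),
    spec("tests.AI_CONCURRENT.sens_by_stage.I",    "beta", 0.89, 0.71, 1.00),
    spec("tests.AI_CONCURRENT.sens_by_stage.II",   "beta", 0.99, 0.95, 1.00),
    spec("tests.AI_CONCURRENT.sens_by_stage.III",  "beta", 0.99, 0.95, 1.00),
    spec("tests.AI_CONCURRENT.specificity",        "beta", 0.93, 0.90, 1.00),
    spec("tests.AI_TRIAGE.sens_by_stage.DCIS", "beta", 0.17,  0.13, 0.20),
    spec("tests.AI_TRIAGE.sens_by_stage.I",    "beta", 0.63,  0.50, 0.75),
    spec("tests.AI_TRIAGE.sens_by_stage.II",   "beta", 0.93,  0.74, 1.00),
    spec("tests.AI_TRIAGE.sens_by_stage.III",  "beta", 0.99,  0.95, 1.00),
    spec("tests.AI_TRIAGE.specificity",        "beta", 0.966, 0.95, 1.00),
    spec("biopsy.sensitivity", "beta", 1.00, 0.95, 1.00),
    spec("biopsy.specificity", "beta", 1.00, 0.95, 1.00),
    spec("utils.u_state.DCIS", "lognormal", 0.61, 0.52, 0.70),
    spec("utils.u_state.I",    "lognormal", 0.63, 0.62, 0.65),
    spec("utils.u_state.II",   "lognormal", 0.63, 0.63, 0.64),
    spec("utils.u_state.III",  "lognormal", 0.62, 0.61, 0.64),
    spec("utils.u_state.IV",   "lognormal", 0.55, 0.51, 0.60),
    spec("utils.disutil_fp",     "lognormal", 0.00, 0.00, 0.01),
    spec("utils.disutil_biopsy", "lognormal", 0.00, 0.00, 0.01),
    spec("econ.discount",        "beta", 0.05, 0.04, 0.06),
    spec("econ.cost_mammogram",    "gamma", 7.71,  2.14, 14.98),
    spec("econ.cost_biopsy",       "gamma", 21.67, 1.66, 28.68),
    spec("econ.cost_coordination", "gamma", 0.68,  0.55, 0.82),
    spec("econ.tx_cost_y1.DCIS", "gamma", 409,  327,  491),
    spec("econ.tx_cost_y1.I",    "gamma", 698,  559,  838),
    spec("econ.tx_cost_y1.II",   "gamma", 2406, 1925, 2887),
    spec("econ.tx_cost_y1.III",  "gamma", 3203, 2562, 3844),
    spec("econ.tx_cost_y1.IV",   "gamma", 4136, 3309, 4963),
    spec("econ.tx_cost_y2to5.DCIS", "gamma", 65,   52,   78),
    spec("econ.tx_cost_y2to5.I",    "gamma", 111,  89,   133),
    spec("econ.tx_cost_y2to5.II",   "gamma", 478,  383,  574),
    spec("econ.tx_cost_y2to5.III",  "gamma", 1008, 807,  1210),
    spec("econ.tx_cost_y2to5.IV",   "gamma", 3178, 2542, 3814)
  )
}

#' Load a model configuration, overriding packaged defaults
#'
#' Reads a YAML (or JSON) file whose fields mirror the structure of
#' [default_config()] and merges it over the packaged baselines; fields not
#' present in the file keep their defaults. An empty or missing `path`
#' returns the defaults unchanged. Validation failures are collected and
#' reported together, not one at a time.
#'
#' @param path path to a YAML or JSON configuration file, or `NULL`.
#' @param overrides an optional named nested list merged after the file,
#'   convenient for programmatic tweaks
#'   (e.g. `list(settings = list(n_individuals = 1000))`).
#' @return a validated `msim_config`.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::yaml.load_file(path)
    cfg <- merge_config(cfg, raw)
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  validate_config(cfg)
  cfg
}

# recursive merge of override list onto a config; age-band tables given as
# list(low, high, values) replace wholesale, named numeric vectors merge by name
merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.null(base[[nm]])) { base[[nm]] <- over[[nm]]; next }
    b <- base[[nm]]; o <- over[[nm]]
    if (inherits(b, "age_band_table")) {
      base[[nm]] <- if (inherits(o, "age_band_table")) o else ab_from_list(o)
    } else if (is.data.frame(b)) {
      base[[nm]] <- if (is.data.frame(o)) o
        else as.data.frame(o, stringsAsFactors = FALSE)
    } else if (is.list(b) && is.list(o)) {
      base[[nm]] <- merge_config(b, o)
    } else if (!is.null(names(b)) && !is.null(names(o)) &&
               is.numeric(b) && all(names(o) %in% names(b))) {
      b[names(o)] <- unlist(o); base[[nm]] <- b
    } else {
      base[[nm]] <- o
    }
  }
  base
}

#' Validate a model configuration
#'
#' Checks every structural invariant of the configuration (probabilities in
#' \[0,1\], non-negative costs, contiguous age bands covering the simulated
#' ages, discount rates in \[0,1), positive cohort sizes, initial stage
#' distribution summing to 1) and raises a single error enumerating *all*
#' violations.
#'
#' @param cfg an `msim_config`.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  bad <- function(msg) errs <<- c(errs, msg)
  chk_prob <- function(x, name) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1))
      bad(sprintf("%s must be a probability in [0,1] (got %s)",
                  name, paste(format(x), collapse = ", ")))
  }
  chk_pos <- function(x, name) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0))
      bad(sprintf("%s must be >= 0 (got %s)", name,
                  paste(format(x), collapse = ", ")))
  }

  nh <- cfg$nat_hist
  for (p in c("p_dcis_to_I", "p_I_to_II", "p_II_to_III", "p_III_to_IV",
              "p_dcis_regress", "p_sympt_dx_I", "p_sympt_dx_II",
              "p_sympt_dx_III", "p_sympt_dx_IV"))
    chk_prob(nh[[p]], paste0("nat_hist.", p))
  if (is.numeric(nh$p_dcis_to_I) && is.numeric(nh$p_dcis_regress) &&
      !anyNA(c(nh$p_dcis_to_I, nh$p_dcis_regress)) &&
      nh$p_dcis_to_I + nh$p_dcis_regress > 1)
    bad("nat_hist: p_dcis_to_I + p_dcis_regress must be <= 1")
  chk_prob(nh$onset_by_age$values, "nat_hist.onset_by_age")

  mt <- cfg$mortality
  chk_prob(mt$allcause_by_age$values, "mortality.allcause_by_age")
  chk_prob(mt$p_bc_death_stageIV_y1, "mortality.p_bc_death_stageIV_y1")
  chk_prob(mt$p_bc_death_stageIV_y2to5, "mortality.p_bc_death_stageIV_y2to5")
  chk_prob(mt$relapse_y1, "mortality.relapse_y1")
  chk_prob(mt$relapse_y2to5, "mortality.relapse_y2to5")

  for (m in names(cfg$tests)) {
    chk_prob(cfg$tests[[m]]$sens_by_stage, paste0("tests.", m, ".sens_by_stage"))
    chk_prob(cfg$tests[[m]]$specificity, paste0("tests.", m, ".specificity"))
  }
  chk_prob(cfg$biopsy$sensitivity, "biopsy.sensitivity")
  chk_prob(cfg$biopsy$specificity, "biopsy.specificity")
  chk_prob(cfg$screening$p_fp_biopsy, "screening.p_fp_biopsy")

  ec <- cfg$econ
  for (p in c("cost_mammogram", "cost_biopsy", "cost_coordination",
              "cost_ai_per_screen", "tx_cost_y1", "tx_cost_y2to5",
              "cost_survivor_annual"))
    chk_pos(ec[[p]], paste0("econ.", p))
  for (p in c("discount_cost", "discount_effect")) {
    x <- ec[[p]]
    if (!is.numeric(x) || anyNA(x) || x < 0 || x >= 1)
      bad(sprintf("econ.%s must be in [0,1)", p))
  }

  ut <- cfg$utils
  chk_prob(ut$u_healthy_by_age$values, "utils.u_healthy_by_age")
  chk_prob(ut$u_state, "utils.u_state")
  chk_prob(ut$disutil_fp, "utils.disutil_fp")
  chk_prob(ut$disutil_biopsy, "utils.disutil_biopsy")
  if (!ut$u_survivor_policy %in% c("age_matched_healthy", "fixed_value"))
    bad("utils.u_survivor_policy must be 'age_matched_healthy' or 'fixed_value'")

  st <- cfg$settings
  if (!is.numeric(st$n_individuals) || is.na(st$n_individuals) ||
      st$n_individuals < 1)
    bad("settings.n_individuals must be >= 1")
  if (!is.numeric(st$n_cycles) || is.na(st$n_cycles) || st$n_cycles < 1)
    bad("settings.n_cycles must be >= 1")
  chk_prob(st$intake_rate, "settings.intake_rate")

  # all simulated ages must be coverable by the band tables
  if (length(errs) == 0L) {
    max_age <- st$start_age + st$n_cycles - 1L
    for (tb in list(c("mortality", "allcause_by_age"),
                    c("nat_hist", "onset_by_age"),
                    c("utils", "u_healthy_by_age"))) {
      tab <- cfg[[tb[1L]]][[tb[2L]]]
      if (st$start_age < tab$low[1L])
        bad(sprintf("%s.%s does not cover the start age %d",
                    tb[1L], tb[2L], st$start_age))
    }
  }

  isd <- cfg$init_stage_distribution
  if (abs(sum(isd) - 1) > 1e-9)
    bad("init_stage_distribution must sum to 1")

  if (length(errs) > 0L)
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.msim_config <- function(x, ...) {
  st <- x$settings
  cat("Breast-cancer screening microsimulation configuration\n")
  cat(sprintf("  cohort: %d women, %d annual cycles from age %d\n",
              st$n_individuals, st$n_cycles, st$start_age))
  cat(sprintf("  screening window: ages %d-%d, intake rate %.2f\n",
              st$start_age, st$screen_stop_age, st$intake_rate))
  cat(sprintf("  discounting: costs %.1f%%, effects %.1f%%/yr; WTP %s USD/QALY\n",
              100 * x$econ$discount_cost, 100 * x$econ$discount_effect,
              format(st$wtp, big.mark = ",")))
  cat(sprintf("  PSA distributions: %d parameters\n", nrow(x$distributions)))
  invisible(x)
}

#' Write a configuration to YAML
#'
#' Serializes an `msim_config` so that [load_config()] on the result
#' reproduces the object exactly (round trip).
#'
#' @param cfg an `msim_config`.
#' @param path output file path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  ser <- function(v) {
    if (inherits(v, "age_band_table")) ab_to_list(v)
    else if (is.data.frame(v)) as.list(v)
    else if (is.list(v)) lapply(v, ser)
    else if (!is.null(names(v))) as.list(v)
    else v
  }
  x <- lapply(x, ser)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else
    yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

# --- parameter path helpers (dot-separated, used by PSA and DSA) -----------

config_get <- function(cfg, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  x <- cfg
  for (p in parts) x <- x[[p]]
  x
}

config_set <- function(cfg, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  set_rec <- function(x, parts, value) {
    if (length(parts) == 1L) { x[[parts]] <- value; return(x) }
    if (is.null(x[[parts[1L]]]))
      stop("unknown parameter path component: ", parts[1L])
    x[[parts[1L]]] <- set_rec(x[[parts[1L]]], parts[-1L], value)
    x
  }
  # "econ.discount" fans out to both discount rates (single printed row)
  if (path == "econ.discount") {
    cfg$econ$discount_cost <- value
    cfg$econ$discount_effect <- value
    return(cfg)
  }
  set_rec(cfg, parts, value)
}
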