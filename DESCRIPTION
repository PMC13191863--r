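Package: mammosim
Title: Individual-Level Microsimulation of Breast Cancer Screening and
    Cost-Effectiveness Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the natural history of breast cancer (healthy, ductal
    carcinoma in situ, invasive stages I-IV, post-treatment survivorship and
    competing mortality) for individual women in annual cycles, overlays
    mammography-based screening strategies including AI-assisted reading
    workflows, and evaluates them economically from a payer perspective.
    Provides the full cost-effectiveness tool chain: discounted cost and QALY
    accounting, the incremental cost-effectiveness frontier with strict and
    extended dominance, net monetary benefit, probabilistic sensitivity
    analysis with cost-effectiveness acceptability frontiers, deterministic
    scenario (tornado) analysis, cohort-size convergence diagnostics, and
    calibration of age-specific disease onset to registry incidence targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
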