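---
title: "Model and methods: breast-cancer screening microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: breast-cancer screening microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mammosim` is an individual-level (first-order Monte Carlo) state-transition
model of breast-cancer natural history in a cohort of women followed in
annual cycles, with a screening layer, a payer-perspective economic layer,
and the decision-analytic machinery — dominance frontier, probabilistic and
deterministic sensitivity analysis, calibration — needed to compare
screening policies. This vignette explains the model, its assumptions, the
parameters that matter, and the numerical choices the implementation makes
where the underlying evidence is silent.

## Health states and the annual transition kernel

Each woman occupies one of nine mutually exclusive states: healthy, ductal
carcinoma in situ (DCIS), invasive stages I--IV, post-treatment survivor,
dead of breast cancer, dead of other causes. Two flags travel with the
clinical state: whether the disease has been *detected* (diagnosed), and
the integer years since diagnosis.

Within a cycle, competing events are resolved as *sequential conditional
Bernoulli draws* in a fixed order:

1. other-cause death, at the age-band all-cause probability (all living
   states);
2. breast-cancer death, for detected stage IV — the first-year probability
   (0.743) in the diagnosis year, the years-2-to-5 probability (0.264)
   thereafter;
3. symptomatic diagnosis of undetected invasive disease (stage I 0.025,
   II 0.22, III 0.55 per year; stage IV with certainty — metastatic
   disease is assumed clinically evident, no published rate exists);
4. progression or regression of undetected disease: healthy → DCIS at the
   calibrated age-specific onset probability; DCIS → stage I (0.21) or
   DCIS → healthy (0.25) as one categorical draw; stage progression
   I→II 0.24, II→III 0.29, III→IV 0.50;
5. relapse of treated stages I--III to detected stage IV, at the
   year-specific relapse probability (year 1 vs years 2--5);
6. the post-diagnosis clock advances; after five treated years the woman
   becomes a survivor, facing general-population mortality only, with the
   age-matched population utility.

The sequential scheme makes every published value directly interpretable
as a conditional per-cycle probability; the exact categorical distribution
it implies is exposed as `transition_row()`, and the engine applies the
identical scheme vectorized with one independent uniform deviate per event
class, which yields the same distribution. Choices worth flagging:

* **Treated disease does not progress through stages.** Treatment halts
  the natural-history chain; the only disease exit from treated stages
  I--III is relapse, which routes to detected stage IV with the clock
  reset — only stage IV carries breast-cancer mortality, so relapse must
  pass through it.
* **Symptomatic stage-IV diagnosis and its first mortality draw occur one
  cycle apart.** The first-year mortality applies at the woman's next
  transition, so each treatment year carries exactly one risk draw. The
  alternative (a same-cycle death draw at diagnosis) would double-apply
  year-1 risk or skip the year-1 cost; the difference is one cycle of
  timing for a minority of cases.
* **DCIS is screen-detectable only** — no symptomatic-diagnosis rate for
  DCIS is published, so none is modelled.
* **Stage IV survivors**: a detected stage-IV woman who survives five
  years becomes a survivor like any other stage (a documented switch in
  the treated-state clock, not separately parameterized).
* Treated stages I--III carry no excess non-relapse cancer mortality in
  years 1--5; none is published.

## The onset schedule and calibration

The transition from healthy to DCIS has no direct epidemiological
estimate; it is the model's calibrated quantity. The packaged age-band
onset schedule (8 five-year bands, 40--79) is the calibrated set carried
by the parameter table, and the same schedule is stored as
`incidence_targets` so the calibration machinery can be exercised against
a printed target set.

`calibrate_onset()` implements a damped multiplicative fixed point: with
common random numbers (a fixed seed shared by every iteration), each
band's onset is multiplied by `(target / predicted)^damp` until the worst
band error drops below the tolerance (default 5%) or the iteration cap is
reached, in which case the best iterate is returned with a warning.
Incidence is measured as new entries into any invasive stage divided by
person-years alive and invasive-free in the band. Numerical behaviour to
be aware of: with 10,000 women, one event in the smallest band is ~4% of
its target, so the max-band criterion can oscillate on discreteness for
some seeds while the scale-free fit quality (percent RMSD, typically
1--5%) is unaffected; per-band parameter *recovery* additionally needs a
start near the truth and a cohort of ~20,000+, because incidence in one
band partly reflects onset in the previous band (the DCIS sojourn,
mean ≈ 2.2 years, shifts events across band boundaries).

## Screening layer

Ten strategies: no screening; mammography read by a radiologist; read
concurrently by an AI system and a radiologist (positive if either
flags); and AI triage with radiologist confirmation (positive only if
both agree) — each at annual, biennial or triennial intervals from age 40
through 75. The per-modality stage-specific sensitivity/specificity
blocks already encode the combined reading rules and are used verbatim;
`compose_readers()` exists for exploring hypothetical operating points
but is not on the baseline path.

Attendance is an independent Bernoulli(0.8) per due screen — the weaker
assumption compared with a fixed 80% subpopulation, and the only reading
the single published intake rate supports; non-attenders may attend later
rounds. Screening happens at the start of the cycle, before that cycle's
transition: a cancer detected this cycle accrues its first-year treatment
cost this cycle. Every screen-positive woman proceeds to core-needle
biopsy (false positives with the configurable false-positive-to-biopsy
probability, 1.0 at baseline); biopsy is perfectly accurate at baseline,
so detection requires true disease. Screen-detected DCIS is additionally
classified against the *untreated counterfactual* simulated on an
independent child random stream: if the counterfactual lesion regresses,
or the woman dies of other causes before it invades, the detection is an
overdiagnosis — a reporting quantity that does not alter the trajectory,
though its costs and disutilities stay in the ledgers, which is precisely
how overdiagnosis burdens the comparison.

## Economic layer

Costs (2023 USD, payer perspective): mammogram 7.71 plus coordination
0.68 per attended screen, plus a per-screen AI cost for the AI modalities
— defaulting to 1.50 USD as an explicit placeholder, since no tariff for
AI reading exists; it is a first-class configuration field and a scenario
parameter, and any conclusions sensitive to it should be re-run with a
local estimate. Biopsy costs 21.67. Stage-specific treatment costs apply
in the first year after diagnosis and annually in years 2--5; survivors
cost `cost_survivor_annual` (default 0 — survivor care is mentioned but
never valued). Undetected disease costs nothing.

Utilities: healthy women carry the age-band population norms (0.75 /
0.71 / 0.68 / 0.65); disease states carry their published weights
regardless of detection (DCIS 0.61, stages I--IV 0.63/0.63/0.62/0.55);
survivors return to the age-matched norm (policy switch for a fixed
value); the dead contribute 0. False-positive anxiety and biopsy
disutilities (0 at baseline, varied in sensitivity analysis) subtract
once in the event cycle, floored at zero.

Discounting is end-of-cycle at 5%/year for both costs and effects, with
the first cycle undiscounted — `(1+r)^-(t-1)` — switchable via
`discount_first_cycle`; there is no half-cycle correction (annual
individual-level cycles, and the convention is under-determined by the
source evidence either way).

## Engine, common random numbers, and determinism

`run_cohort()` pre-draws all randomness from the run seed as eight
per-purpose uniform matrices (attendance, imaging, biopsy, other-cause
death, cancer death, symptomatic diagnosis, progression, relapse — in
that fixed order), then sweeps the cohort cycle by cycle with vectorized
masks. Consequences: a given `(config, strategy, seed)` is bit-for-bit
reproducible, and two strategies run under the same seed share every
woman's life-course uniforms — strategy contrasts are paired (common
random numbers), which is what makes small incremental effects estimable
at desk scale. Overdiagnosis counterfactuals use per-woman child seeds so
they perturb nothing else. A cohort of 10,000 women over 40 cycles runs
in roughly a second in pure R; the cost is dominated by drawing ~3.2
million uniforms.

Women enter healthy at 40. The published stage distribution "at the
commencement of the modeling process" (I 11%, II 51%, III 31%, IV 7%) is
treated as a *validation target* for the stage mix at symptomatic
diagnosis — which the model reproduces (≈10/47/30/13) — not as seeded
prevalence; a `seed_prevalent_disease` switch with an explicit
`prevalent_fraction` exists to explore the alternative reading, but no
prevalent fraction is published, so the default keeps the cohort
disease-free at entry.

## Decision layer

`build_frontier()` sorts strategies by effect (ties to lower cost, then
id), marks strict dominance, then iteratively removes extended-dominated
members until the incremental cost-effectiveness ratios strictly
increase. Its independent check in the test suite is a
willingness-to-pay sweep: a strategy is non-dominated iff it maximizes
net monetary benefit (`wtp x effect - cost`) at some threshold; the two
constructions agree on a thousand random instances.

The probabilistic sensitivity analysis samples every parameter with a
published range independently (no correlations are published),
substitutes the draw into a config copy, and runs all strategies under
common random numbers per draw; draws are reproducible from
`(master seed, draw index)`. Range endpoints are read as a central 95%
interval — the standard convention for decision-model parameter tables —
and each family is fitted by pinning its mean to the baseline and
least-squares-matching the 2.5%/97.5% quantiles. Degenerate rows are
coerced: log-normal rows with baseline 0 (the disutilities) and beta rows
with baseline exactly 1 (the biopsy block) become uniform on their range,
flagged `coerced`. Where a printed range is badly asymmetric around its
baseline (one arm more than ~1.8x the other, e.g. the stage II utility
0.63 with range [0.63, 0.64], or the biopsy cost 21.67 with range
[1.66, 28.68]), no mean-pinned distribution can treat it as a central 95%
interval; the fit keeps the mean exact and takes the closest quantiles it
can, and the test suite checks range coverage only for the
near-symmetric rows. Stage-IV screening sensitivity always mirrors the
sampled stage-III value (sensitivity is monotone in stage; no stage-IV
block is published), the single discounting parameter feeds both cost
and effect rates, infeasible DCIS draws (progression + regression > 1)
are redrawn and counted, and calibrated onset probabilities are held
fixed across draws by default (whether they were re-sampled in the
source analysis is unstated; a switch can jitter them).

Deterministic sensitivity analysis re-runs the comparison one parameter
at a time (AI accuracy block, discount rate, false-positive biopsy
probability, false-positive disutility, per-screen AI cost) at
optimistic/conservative values under a fixed engine seed, so the null
scenario reproduces base case exactly; `convergence_scan()` replicates
the headline ICER across seeds at increasing cohort sizes, where the
replicate SD shrinks roughly as `n^-1/2`.

## What the synthetic-data generator does and does not emulate

`generate_synthetic_targets()` produces piecewise-constant five-year-band
incidence with the qualitative age pattern of Iranian female breast
cancer — a rise from 40 to a mid-life plateau and a late-age decline —
plus a monotone increasing all-cause mortality table, for download-free
testing of calibration and the engine. It emulates the *shape* and
*scale* (rates in (0, 0.01)) of registry inputs, not their sampling
noise, cohort effects, or any correlation between incidence and
mortality; a calibration that passes on synthetic targets demonstrates
algorithmic correctness (the fixed point recovers a known onset under
common random numbers), not epidemiological validity of any particular
parameter set.

## Problem sizes used by the checks

The packaged checks run at the scales the analysis itself uses where that
is cheap — 10,000 women x 40 cycles for cohort epidemiology (seed-averaged
over 8 runs), calibration at the full cohort size — and at reduced but
structurally identical scale where the full design would be wasteful for
a correctness check: the reduced probabilistic sensitivity analysis uses
200 draws x 2,000 women (the full 1,000 x 10,000 design is available by
argument), convergence scans use a two-point size grid, and parameter
recovery uses 20,000 women so that single-event discreteness sits well
under the per-band tolerance.

## Known limitations

* No tumour-size or continuous sojourn-time modelling; stages are the
  only disease resolution, and no risk-factor stratification exists —
  heterogeneity beyond age enters only through calibrated onset.
* The cohort is closed and single-aged; there is no population entry,
  so cross-sectional program costs cannot be read off directly.
* Utilities attach to clinical states irrespective of detection, so an
  undetected stage-I cancer carries its state utility before diagnosis;
  the alternative (healthy utility until diagnosis) shifts QALY levels
  by well under 1% but is not currently a switch.
* The published parameter table under-determines several conventions
  (event ordering within a cycle, discounting of the first cycle, the
  prevalent fraction at entry); each is implemented as documented above,
  and the epidemiological counts the model produces are internally
  consistent with its printed transition probabilities — an exact
  deterministic recursion over the kernel reproduces the engine's
  incidence and mortality to Monte-Carlo precision — but conventions
  chosen differently elsewhere will shift absolute counts by tens of
  percent. Comparisons *between* strategies, run under common random
  numbers, are far more stable than absolute levels.
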