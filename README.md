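# tirocea

Cost-effectiveness of intravenous tirofiban versus oral aspirin for acute
ischemic stroke **without large or medium-sized vessel occlusion** — the
population ineligible for thrombectomy and mostly for thrombolysis — from the
healthcare-system perspectives of China and the US. The package is for health
economists and HTA analysts who want the full analysis as inspectable,
testable code: base cases, one-way (tornado) sensitivity, probabilistic
sensitivity analysis, acceptability curves, and subgroup analysis by
life-table substitution.

## The model

A hybrid decision tree + Markov cohort model:

* **Months 0–3 (decision tree).** Each arm receives its trial month-3
  distribution over the modified Rankin Scale (mRS 0–6, 6 = death), plus
  arm-specific acute accruals: tirofiban drug cost
  (weight × (0.4 µg/kg/min × 30 min + 0.1 µg/kg/min × 48 h)), infusion fees,
  grouped acute hospitalisation costs, and symptomatic intracranial
  hemorrhage (p = 0.01, tirofiban only).
* **Cycles 1–79 (Markov).** Seven mRS states, 3-month cycles, 20-year
  horizon. Annual recurrence probability *R* becomes a cycle probability via
  `r = -ln(1-R)/4`, `p = 1-exp(-r)`; post-recurrence death probability 0.21
  (China) / 0.19 (US); recurrence survivors redistribute evenly over
  equal-or-worse states; background mortality is life-table based, scaled by
  disability-specific death hazard ratios (1 … 2.37 for mRS 0 … 5).
* **Outcomes.** Per-arm lifetime cost and QALYs
  (QALY = life-years × state utility, effects discounted at 5%/3%),
  ICER = ΔC/ΔE, net monetary benefit NMB = E·λ − C at λ = 85,698 CNY or
  $100,000 per QALY.

Two engine conventions are deliberately "reproduction-mode" defaults —
annual background mortality applied per quarterly cycle, and undiscounted
costs — because they are what the published totals imply; both are toggles,
and `vignettes/model-methods.Rmd` documents the evidence and the
textbook alternatives.

## Worked example

```r
library(tirocea)

cfg <- load_scenario("china_base")   # Table-1-for-China parameter set
run_scenario(cfg)
#> <cea_result china (CNY), WTP 85,698/QALY>
#>        arm   cost  qaly    nmb
#>    aspirin 103287 3.440 191541
#>  tirofiban 101250 3.605 207677
#>   incr cost -2,037, incr QALY 0.1645, ICER -12,383 per QALY (dominant, quadrant IV)
```

Tirofiban costs 2,037 CNY *less* over 20 years and yields 0.165 more
quality-adjusted life years, so it dominates aspirin (CE-plane quadrant IV);
the negative ICER is reported for display only — dominance, not the ratio, is
the decision-relevant fact. The US base case
(`run_scenario(load_scenario("us_base"))`) is likewise dominant
($200,539 vs $205,828; 4.71 vs 4.59 QALYs, on the shipped *synthetic*
placeholder US life table).

Sensitivity analyses:

```r
tornado(cfg)[1:3, c("parameter", "span")]   # widest one-way ΔNMB spans first
#>         parameter      span
#> 1          u_mrs3 10547.980
#> 2 posthosp_mrs2_5  7293.411
#> 3   discount_rate  6277.025

psa <- run_psa(cfg, n_iterations = 10000, seed = 1)
psa_quadrants(psa)          # CE-plane quadrant fractions
ceac(psa)                   # acceptability vs willingness-to-pay
subgroup_run(cfg, make_life_table(68, 98, 5, 0.0127, 1.6, sex_adjustment = 0.8))
```

## Acceptance script

`scripts/acceptance.R` recomputes the headline quantities from scratch by
running the installed package: both country base cases (per-arm lifetime
costs and QALYs) and a fresh 10,000-draw PSA per country (quadrant-IV share
and acceptability at WTP 0, reported as the minimum across countries), then
writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

* `R/` — parameter model (`dist_spec`, moment matching, scenarios), acute
  phase, Markov engine, CEA outcomes, sensitivity analyses, synthetic
  fixtures, reports.
* `inst/extdata/` — `china_base.yaml`, `us_base.yaml` (the built-in scenarios
  in the config-file schema); `inst/cli/tirocea` — thin command-line front
  end (`basecase`, `sensitivity`, `fixtures`).
* `tests/testthat/` — unit and property tests, including exhaustive
  path-enumeration and microsimulation oracles for the engine, plus the
  acceptance layer in `test-acceptance.R`.
* `vignettes/model-methods.Rmd` — model structure, every convention and
  toggle, distributional choices, synthetic-data scope, limitations.
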