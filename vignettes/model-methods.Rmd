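---
title: "Model structure, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tirocea)
```

## The decision problem

Patients with acute ischemic stroke but no large or medium-sized vessel
occlusion are ineligible for thrombectomy and often for thrombolysis; the
comparison here is intravenous tirofiban (0.4 µg/kg/min for 30 min, then
0.1 µg/kg/min for 48 h) against oral aspirin, from the healthcare-system
perspective of China and of the US. Treatment changes the distribution of
disability at month 3 — measured on the modified Rankin Scale (mRS 0 = no
symptoms … 5 = severe disability, 6 = death) — and everything downstream
(care costs, quality of life, survival) is driven by that distribution.

## Model structure

The model is a hybrid of a decision tree and a Markov cohort model.

**Decision tree (month 0–3).** Each arm is assigned its trial month-3 mRS
distribution. Arm-specific accruals are the drug acquisition cost (22.5 mg
for a 75 kg Chinese patient; 27 mg for a 90 kg US patient), the infusion
administration fee (48.5 h total: first hour plus 48 additional hours), the
expected acute hospitalisation cost grouped by month-3 mRS (China groups
0–1 / 2–5 / death; the US 0–2 / 3–5 / death), and the expected cost and
utility decrement of symptomatic intracranial hemorrhage (probability 0.01 in
the tirofiban arm, 0 under aspirin). The quarter contributes
`0.25 * sum(p_i u_i)` QALYs. Acute accruals are not discounted (year 0).

**Markov model (cycles 1–79).** Seven states (mRS 0–5 and death), 3-month
cycles, 20-year horizon, so the acute quarter plus 79 cycles. Each cycle a
living patient in state *i* may

1. suffer a recurrent stroke (annual probability 0.017 China / 0.013 US,
   converted to a cycle probability via `r = -ln(1-R)/4`, `p = 1-exp(-r)`);
   a fraction (0.21 / 0.19) dies, survivors redistribute evenly over states
   *i*…5 (never to a better state);
2. otherwise die of background causes at the life-table probability for the
   cohort's current age scaled by a disability-specific hazard ratio
   (1, 1, 1.11, 1.27, 1.71, 2.37 for mRS 0–5);
3. otherwise remain in state *i*.

Post-month-3 prognosis is arm-independent: both arms share one transition
engine and differ only through their starting distribution and acute-phase
terms. Living states accrue the post-hospitalisation cost schedule (Chinese
annual group costs spread over four cycles; US per-state quarterly costs),
each recurrence event is charged the recurrent-stroke cost once, and
recurrence survivors accrue the recurrence utility (0.42 China / 0.31 US)
instead of their state utility during that cycle.

## Reproduction-mode conventions

Two conventions in the reference analysis are not the ones its own methods
text implies, and both are exposed as toggles with the published behaviour as
the default:

* **`mortality_conversion = "annual_per_cycle"`.** Applying the stated
  quarterly rate conversion to background mortality yields roughly 5.6/5.4
  discounted QALYs per arm in China — far above the published 3.62/3.48.
  Applying the HR-scaled *annual* death probability in every 3-month cycle
  (i.e. converting only the recurrence rate) reproduces the published QALYs
  to about 1%. That convention quadruples background mortality relative to
  the textbook conversion, and `"quarterly"` selects the textbook formula
  (`adjusted_background_death_prob()`) instead.
* **`discount_costs = FALSE`.** With costs discounted at the stated rates the
  China cost totals come out ~20% below the published ones; with costs left
  undiscounted both arms match within 0.5% (China) and 2% (US). Effects are
  discounted (`discount_effects = TRUE`) in both modes.

The remaining toggles cover conventions the source leaves open: `half_cycle`
(default off: accrual on end-of-cycle membership), `recurrence_includes_source`
(default on: survivors may stay in their own state), `infusion_in_aspirin`
(default off: the aspirin arm received an intravenous placebo, but only the
tirofiban arm is charged infusion fees), and `recurrence_utility_mode`
(default `"absolute"`: the recurrence utility replaces the state utility for
the cycle; `"decrement"` subtracts it). Dominance of tirofiban — lower cost
*and* more QALYs — holds under every combination of these toggles, which the
acceptance tests check exhaustively.

Other fixed choices: the cohort starts at age 68 (the first band of the
printed Chinese life table, so the 20-year horizon spans the printed bands);
ages beyond the last band reuse its probability; the sICH disutility (0.38)
applies for one quarter (`sich_exposure_years`), reading sICH as an event of
the 48-hour treatment window; aspirin acquisition costs are identical in both
arms from hour ~44 onward and are set to 0 (they cancel in increments);
recurrent-stroke decedents are charged the recurrence cost but accrue no
state cost or utility in the death state.

## Parameters and distributions

Every input is a `dist_spec`: point estimate, PSA family, SD, and the one-way
range. Costs are gamma, probabilities and utilities beta, death hazard ratios
natural-scale lognormal truncated below at 1 (their printed ranges never go
below 1), all moment-matched from the printed (value, SD) pairs —
`beta_from_moments()`, `gamma_from_moments()`, `lognormal_from_moments()` are
exact by construction and round-trip to 1e-10. Patient weight is listed with
a beta family but lives on 50–120 kg (China) / 60–150 kg (US); it is sampled
on the range-rescaled unit interval, the only coherent reading of a beta SD
of 12.5 kg. The month-3 mRS distributions follow a Dirichlet with
concentrations `ess * p_i`; no effective sample size is published, so the
default `psa_ess = 579` uses roughly one arm of the 1158-patient source
trial, and the value is a config field. Parameters marked with a range but no
family (the discount rate, the aspirin sICH probability) are fixed in the PSA
and varied only in one-way analysis.

## Sensitivity machinery

One-way analysis pins each ranged parameter at its endpoints (all else at
base) and records the ICER and the incremental net monetary benefit
(`ΔNMB = wtp · ΔQALY − Δcost`) at the national threshold (85,698 CNY;
$100,000). Tornado ordering uses the ΔNMB span: negative ICERs are not
ordered meaningfully, ΔNMB always is.

The PSA draws all parameters independently (no correlation structure is
published). Parameters shared by the arms — costs, utilities, hazard ratios,
recurrence — use one common draw per iteration; the month-3 distributions and
the sICH probability are arm-specific. Each parameter owns a seed substream
derived from the master seed by hashing its name, so runs are bitwise
reproducible and adding a parameter does not perturb the others' draws.

A caveat the package measures rather than hides: from the printed
dispersions, the share of PSA draws in cost-effectiveness-plane quadrant IV
is far below the published ">95%". The printed SDs of the
post-hospitalisation costs (e.g. SD 3356 on the Chinese mRS 2–5 annual cost),
sampled once per draw and multiplying the arms' *different* lifetime
state-mix exposures, put an SD on the incremental cost comparable to the mean
saving itself; even with the Dirichlet noise removed entirely the quadrant-IV
share stays in the low 80s. The acceptance suite keeps the published claim as
its threshold and reports the measured fractions; acceptability at the
national WTP threshold (rather than at WTP 0) does reach the mid-90s in
China.

## Synthetic data

`make_life_table()` produces banded Gompertz-like mortality
(`base * growth^band * sex_adjustment`, capped at 1 with a warning). The US
scenario ships `us_placeholder_life_table()` — 5-year bands from age 68, base
0.013, growth 1.62 per band — because the source's US life table is
non-public supplementary material. It is **synthetic**, chosen once to
bracket the growth pattern of the printed Chinese bands, and is why US
absolute levels carry a ±15% tolerance where China carries ±10%: with it, US
costs reproduce within 2% but US QALYs sit ~13% above the published values
(consistent with true US mortality at these ages being somewhat higher than
the placeholder's). Any user-supplied life table can replace it via
`subgroup_run()`.

`make_null_scenario()` makes the arms identical (shared month-3 distribution,
no sICH, zero drug/infusion prices): every increment is exactly 0, a PSA
under shared draws sits on the CE-plane origin, and one-way spans vanish —
certifying that nothing arm-specific leaks through the pipeline.
`make_oracle_scenario()` builds collapsed 2–4-state instances over 2–6 cycles
whose totals are recomputed exhaustively by path enumeration in the test
suite.

What a green test does *not* establish: the generator emulates the cohort
world of the model (homogeneous ageing, independent parameters, no secular
trends in costs or mortality, no treatment-effect waning), so agreement with
its oracles certifies the arithmetic, not the external validity of the
published inputs.

## Validation summary

The test suite checks, among others: transition rows sum to 1 and never move
mass to better states; cohort propagation equals explicit
transition-matrix products; engine totals equal exhaustive path enumeration
on collapsed scenarios to 1e-10 and an independent 60,000-patient
microsimulation within 3 Monte-Carlo SEs; closed-form QALYs in degenerate
scenarios (no mortality; constant-hazard geometric series); moment-matching
round trips; PSA reproducibility and support constraints; and the base-case
reproduction tolerances above. Run `testthat::test_dir("tests/testthat")` or
`devtools::test()`.

## Known limitations

* No half-cycle correction by default and no tunnel states; one recurrence
  per cycle at most; recurrence history beyond the event cycle is not
  tracked.
* The mRS-improvement ban (recommended by the source's neurologists) likely
  overstates long-run care costs for both arms.
* The US background-mortality placeholder is synthetic (above).
* The reproduction-mode defaults intentionally mirror the published engine's
  behaviour, including its departure from the textbook mortality conversion
  and cost discounting; switch the toggles for a methodologically
  conventional analysis.
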