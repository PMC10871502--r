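Package: tirocea
Title: Cost-Effectiveness of Intravenous Tirofiban for Acute Ischemic Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid decision-tree plus Markov cohort model comparing intravenous
    tirofiban with oral aspirin in acute ischemic stroke without large or
    medium-sized vessel occlusion. Implements seven modified Rankin Scale (mRS)
    health states on 3-month cycles over a 20-year horizon, with recurrent
    stroke, hazard-ratio-adjusted background mortality, symptomatic intracranial
    hemorrhage, and country-specific (China, US) costs and utilities. Provides
    base-case cost-effectiveness outcomes (costs, QALYs, ICER, net monetary
    benefit), one-way sensitivity analysis with tornado ordering, 10,000-draw
    probabilistic sensitivity analysis with moment-matched beta, gamma,
    lognormal and Dirichlet distributions, cost-effectiveness acceptability
    curves, and subgroup analysis by life-table substitution.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
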