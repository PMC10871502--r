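test_that("annual-to-cycle probability conversion matches the rate formulas", {
  expect_equal(annual_rate_to_cycle_prob(0.017), 0.00427736561, tolerance = 1e-9)
  expect_equal(annual_rate_to_cycle_prob(0.013), 0.003265964983, tolerance = 1e-9)
  expect_equal(annual_rate_to_cycle_prob(0), 0)
  # four cycles recompose the annual probability
  p <- annual_rate_to_cycle_prob(0.3)
  expect_equal(1 - (1 - p)^4, 0.3, tolerance = 1e-12)
  expect_error(annual_rate_to_cycle_prob(1), "\\[0, 1\\)")
})

test_that("HR-adjusted background death probability scales on the rate scale", {
  expect_equal(adjusted_background_death_prob(0.01266, 1), 0.003180137778, tolerance = 1e-9)
  expect_equal(adjusted_background_death_prob(0.01266, 2.37), 0.007520514579, tolerance = 1e-9)
  # hr = 1 reduces to the plain conversion, for any probability
  for (p in c(0.001, 0.0634, 0.1512)) {
    expect_equal(adjusted_background_death_prob(p, 1), annual_rate_to_cycle_prob(p),
                 tolerance = 1e-14)
  }
  expect_error(adjusted_background_death_prob(1.01, 1), "\\[0, 1\\)")
})

test_that("discount factors follow (1+r)^-t", {
  expect_equal(discount_factor(0, 0:10), rep(1, 11))
  expect_equal(discount_factor(0.05, 4), 1 / 1.05, tolerance = 1e-12)
  expect_equal(discount_factor(0.03, 80), 0.5536757542, tolerance = 1e-9)
})

test_that("transition matrix rows are stochastic, absorbing in death, never improving", {
  q <- annual_rate_to_cycle_prob(0.017)
  d <- 0.21
  b <- adjusted_background_death_prob(0.01266, c(1, 1, 1.11, 1.27, 1.71, 2.37))
  M <- build_transition_matrix(q, d, b)
  expect_equal(rowSums(M), rep(1, 7), tolerance = 1e-12)
  expect_true(all(M >= 0 & M <= 1))
  expect_equal(M[7, ], c(rep(0, 6), 1))
  expect_true(all(M[lower.tri(M)] == 0))  # never to a lower disability level

  # worked row for mRS 2: death column and the even redistribution mass
  expect_equal(M[3, 7], 0.004412485457, tolerance = 1e-9)
  expect_equal(M[3, 4], q * (1 - d) / 4, tolerance = 1e-14)
  expect_equal(M[3, 4], 0.0008447797081, tolerance = 1e-9)
  # from the worst living state, recurrence survivors have nowhere worse to go
  expect_equal(M[6, 6], q * (1 - d) + (1 - q) * (1 - b[6]), tolerance = 1e-14)

  # no recurrence: diagonal plus the death column only
  M0 <- build_transition_matrix(0, d, b)
  off <- M0; diag(off) <- 0; off[, 7] <- 0
  expect_true(all(off == 0))

  # excluding the source state shifts the redistribution but stays stochastic
  Mx <- build_transition_matrix(q, d, b, include_source = FALSE)
  expect_equal(rowSums(Mx), rep(1, 7), tolerance = 1e-12)
  expect_equal(Mx[3, 4], q * (1 - d) / 3, tolerance = 1e-14)
})

test_that("cohort propagation conserves mass, death is monotone, and matches the matrix route", {
  cfg <- china_base()
  init <- as.numeric(cfg$mrs_month3$tirofiban)
  trace <- run_cohort(init, cfg)
  occ <- as.matrix(trace[, paste0("mrs", 0:6)])
  expect_equal(rowSums(occ), rep(1, nrow(occ)), tolerance = 1e-9)
  expect_true(all(diff(occ[, "mrs6"]) >= -1e-12))
  expect_equal(nrow(occ), 80)  # cycle 0 (month 3) + 79 Markov cycles

  # independent route: explicit matrix products with the same per-cycle inputs
  vals <- base_values(cfg)
  q <- annual_rate_to_cycle_prob(vals[["p_recurrent_annual"]])
  hr <- vals[paste0("hr_mrs", 0:5)]
  v <- init
  for (k in 1:79) {
    pa <- life_table_lookup(cfg$life_table, 68 + 0.25 * k)
    b <- 1 - (1 - pa)^hr  # annual-per-cycle reproduction convention
    v <- as.numeric(v %*% build_transition_matrix(q, vals[["p_death_after_recurrence"]], b))
  }
  expect_equal(as.numeric(occ[80, ]), v, tolerance = 1e-12)
})

test_that("degenerate cohorts have closed-form accruals", {
  # no mortality, no recurrence, no discounting: QALY = u0 * (horizon - 0.25)
  cfg <- make_oracle_scenario(n_states = 2, n_cycles = 4, seed = 5)
  cfg$horizon_years <- 20
  cfg$params$p_recurrent_annual <- dist_spec("p_recurrent_annual", 0, "fixed")
  cfg$params$discount_rate <- dist_spec("discount_rate", 0, "fixed", low = 0, high = 0.08)
  cfg$life_table <- life_table(70, 120, 0)
  u0 <- cfg$params$u_s0$base
  trace <- run_cohort(c(1, 0), cfg)
  tot <- attr(trace, "totals")
  expect_equal(tot[["qaly"]], u0 * (20 - 0.25), tolerance = 1e-10)

  # constant death probability, no costs: geometric-series QALY
  k <- 6
  cfg2 <- make_oracle_scenario(n_states = 2, n_cycles = k, seed = 5)
  dthp <- 0.07
  cfg2$params$p_recurrent_annual <- dist_spec("p_recurrent_annual", 0, "fixed")
  cfg2$params$discount_rate <- dist_spec("discount_rate", 0, "fixed", low = 0, high = 0.08)
  cfg2$params$posthosp_s0 <- dist_spec("posthosp_s0", 0, "fixed")
  cfg2$life_table <- life_table(70, 120, dthp)
  tot2 <- attr(run_cohort(c(1, 0), cfg2), "totals")
  expect_equal(tot2[["qaly"]],
               cfg2$params$u_s0$base * 0.25 * sum((1 - dthp)^(1:k)), tolerance = 1e-10)
  expect_equal(tot2[["cost"]], 0)
})

test_that("zero discount equals the undiscounted sum of accruals; survivors' mix is stable", {
  cfg <- china_base()
  cfg$toggles$discount_costs <- TRUE
  vals <- base_values(cfg)
  vals[["discount_rate"]] <- 0
  init <- as.numeric(cfg$mrs_month3$aspirin)
  trace <- run_cohort(init, cfg, vals)
  tot <- attr(trace, "totals")
  # rate 0 with discounting enabled == discounting disabled entirely
  cfg_off <- china_base()
  cfg_off$toggles$discount_costs <- FALSE
  cfg_off$toggles$discount_effects <- FALSE
  tot_off <- attr(run_cohort(init, cfg_off, vals), "totals")
  expect_equal(tot[["cost"]], tot_off[["cost"]], tolerance = 1e-12)
  expect_equal(tot[["qaly"]], tot_off[["qaly"]], tolerance = 1e-12)
  expect_equal(tot[["cost"]], sum(trace$cost), tolerance = 1e-9)

  # no recurrence + equal HRs: proportions among survivors never change
  vals2 <- base_values(cfg)
  vals2[["p_recurrent_annual"]] <- 0
  vals2[paste0("hr_mrs", 0:5)] <- 1
  tr2 <- run_cohort(init, cfg, vals2)
  occ <- as.matrix(tr2[, paste0("mrs", 0:5)])
  props <- occ / rowSums(occ)
  expect_equal(props[80, ], props[1, ], tolerance = 1e-10)
})

test_that("monotonicity: worse hazards lower QALYs, more recurrence raises recurrence cost", {
  cfg <- china_base()
  init <- as.numeric(cfg$mrs_month3$aspirin)
  vals <- base_values(cfg)
  base_tot <- attr(run_cohort(init, cfg, vals), "totals")

  vals_hr <- vals
  vals_hr[paste0("hr_mrs", 2:5)] <- vals[paste0("hr_mrs", 2:5)] * 1.5
  expect_lt(attr(run_cohort(init, cfg, vals_hr), "totals")[["qaly"]], base_tot[["qaly"]])

  rec_cost <- function(v) {
    tr <- run_cohort(init, cfg, v)
    sum(tr$recurrence_events) * v[["cost_recurrent"]]
  }
  vals_q <- vals
  vals_q[["p_recurrent_annual"]] <- 0.04
  expect_gt(rec_cost(vals_q), rec_cost(vals))
})

test_that("engine equals the exhaustive path-enumeration oracle on collapsed scenarios", {
  for (seed in 1:3) {
    cfg <- make_oracle_scenario(n_states = 3, n_cycles = 4, seed = seed)
    init <- as.numeric(cfg$mrs_month3$tirofiban)
    tot <- attr(run_cohort(init, cfg), "totals")
    oracle <- path_enum_totals(cfg, init)
    expect_equal(tot[["cost"]], oracle[["cost"]], tolerance = 1e-10)
    expect_equal(tot[["qaly"]], oracle[["qaly"]], tolerance = 1e-10)
  }

  # discounting on, source state excluded, quarterly mortality conversion
  cfg <- make_oracle_scenario(n_states = 4, n_cycles = 5, seed = 9)
  cfg$toggles$discount_costs <- TRUE
  cfg$toggles$recurrence_includes_source <- FALSE
  cfg$toggles$mortality_conversion <- "quarterly"
  init <- as.numeric(cfg$mrs_month3$aspirin)
  tot <- attr(run_cohort(init, cfg), "totals")
  oracle <- path_enum_totals(cfg, init)
  expect_equal(tot[["cost"]], oracle[["cost"]], tolerance = 1e-10)
  expect_equal(tot[["qaly"]], oracle[["qaly"]], tolerance = 1e-10)
})

test_that("trace exports to CSV with one row per cycle", {
  cfg <- china_base()
  trace <- run_cohort(as.numeric(cfg$mrs_month3$tirofiban), cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(trace, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 80)
  expect_equal(back$mrs6, trace$mrs6, tolerance = 1e-12)
})
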