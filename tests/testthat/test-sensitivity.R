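test_that("one-way records pin range endpoints and degenerate ranges span zero", {
  cfg <- china_base()
  rec <- one_way(cfg, "discount_rate")
  expect_equal(rec$low_input, 0)
  expect_equal(rec$high_input, 0.08)
  expect_true(rec$dnmb_low > 0 && rec$dnmb_high > 0)

  cfg$params$u_mrs0 <- dist_spec("u_mrs0", 0.95, "beta", sd = 0.005,
                                 low = 0.95, high = 0.95)
  degen <- one_way(cfg, "u_mrs0")
  expect_equal(degen$span, 0, tolerance = 1e-9)
  expect_error(one_way(cfg, "p_sich_aspirin"), "no published range")
  expect_error(one_way(cfg, "nonexistent"), "unknown parameter")
})

test_that("tornado covers every ranged parameter, ordered by span, order-invariant", {
  cfg <- china_base()
  tor <- tornado(cfg)
  expect_equal(nrow(tor), length(ranged_parameters(cfg)))
  expect_true(all(diff(tor$span) <= 1e-12))
  # permuting the parameter list does not change the ordering
  cfg2 <- cfg
  cfg2$params <- cfg2$params[rev(names(cfg2$params))]
  expect_equal(tornado(cfg2)$parameter, tor$parameter)
})

test_that("PSA is reproducible, respects supports, and quadrants partition the draws", {
  cfg <- china_base()
  p1 <- run_psa(cfg, 150, seed = 7)
  p2 <- run_psa(cfg, 150, seed = 7)
  expect_identical(p1$samples, p2$samples)
  p3 <- run_psa(cfg, 150, seed = 8)
  expect_false(identical(p1$samples$incr_cost, p3$samples$incr_cost))

  d <- p1$param_draws
  expect_true(all(d[, "p_sich_tirofiban"] >= 0 & d[, "p_sich_tirofiban"] <= 1))
  expect_true(all(d[, paste0("hr_mrs", 0:5)] >= 1))
  expect_true(all(d[, "weight_kg"] >= 50 & d[, "weight_kg"] <= 120))
  expect_true(all(d[, c("cost_recurrent", "posthosp_mrs2_5")] >= 0))
  expect_true(all(d[, "p_sich_aspirin"] == 0))        # fixed, never sampled
  expect_true(all(d[, "discount_rate"] == 0.05))      # fixed, never sampled
  expect_equal(sum(table(p1$samples$quadrant)), 150)
  expect_equal(sum(psa_quadrants(p1)), 1, tolerance = 1e-12)
})

test_that("PSA parameter substreams hit the published means", {
  cfg <- china_base()
  n <- 40000
  for (nm in c("u_mrs2", "posthosp_mrs2_5", "p_recurrent_annual", "weight_kg")) {
    spec <- cfg$params[[nm]]
    x <- tirocea:::draw_param(spec, n, master_seed = 123)
    expect_lt(abs(mean(x) - spec$base), 3 * spec$sd / sqrt(n))
  }
  # Dirichlet marginals center on the month-3 distribution
  m <- tirocea:::draw_mrs(cfg$mrs_month3$tirofiban, cfg$psa_ess, n, 123, "mrs_tirofiban")
  p <- as.numeric(cfg$mrs_month3$tirofiban)
  se <- sqrt(p * (1 - p) / (cfg$psa_ess + 1)) / sqrt(n)
  expect_true(all(abs(colMeans(m) - p) < 4 * se))
  expect_equal(rowSums(m), rep(1, n), tolerance = 1e-12)
})

test_that("CEAC follows its definition, includes WTP 0, and rises with a mean QALY gain", {
  cfg <- china_base()
  psa <- run_psa(cfg, 400, seed = 3)
  curve <- ceac(psa, wtp_grid = seq(0, 2e5, by = 2e4))
  expect_equal(curve$acceptability[curve$wtp == 0], mean(psa$samples$incr_cost < 0))
  expect_gt(mean(psa$samples$incr_qaly), 0)
  expect_error(ceac(psa, wtp_grid = c(1e4, 2e4)), "include 0")

  # monotone in WTP once every draw carries a QALY gain (quadrant-III draws,
  # which are cost-saving but QALY-losing, legitimately drop out as WTP rises)
  pos <- psa
  pos$samples <- psa$samples[psa$samples$incr_qaly > 0, ]
  pos$n <- nrow(pos$samples)
  cpos <- ceac(pos, wtp_grid = seq(0, 2e5, by = 2e4))
  expect_true(all(diff(cpos$acceptability) >= -1e-12))

  # an all-dominant sample set is accepted everywhere
  psa$samples$incr_cost <- -abs(psa$samples$incr_cost) - 1
  psa$samples$incr_qaly <- abs(psa$samples$incr_qaly) + 1e-9
  expect_true(all(ceac(psa, c(0, 5e4, 1e5))$acceptability == 1))
})

test_that("null scenario: zero increments, PSA at the origin under shared draws, flat one-way", {
  null <- make_null_scenario()
  res <- run_scenario(null)
  expect_equal(res$incr_cost, 0, tolerance = 1e-9)
  expect_equal(res$incr_qaly, 0, tolerance = 1e-12)
  expect_equal(res$icer$flag, "undefined")

  psa <- run_psa(null, 60, seed = 2, share_arm_draws = TRUE)
  expect_equal(psa$samples$incr_cost, rep(0, 60), tolerance = 1e-9)
  expect_equal(psa$samples$incr_qaly, rep(0, 60), tolerance = 1e-12)

  ow <- one_way(null, "posthosp_mrs2_5")
  expect_equal(ow$span, 0, tolerance = 1e-9)
})

test_that("subgroup life-table substitution: identity override, mortality monotonicity", {
  cfg <- china_base()
  base <- run_scenario(cfg)
  same <- subgroup_run(cfg, life_table_override = china_life_table())
  expect_equal(same$arms$qaly, base$arms$qaly, tolerance = 1e-12)

  harsher <- life_table(c(68, 70, 75, 80, 85), c(69, 74, 79, 84, 89),
                        pmin(1, china_life_table()$annual_death_prob * 2))
  worse <- subgroup_run(cfg, life_table_override = harsher)
  expect_true(all(worse$arms$qaly < base$arms$qaly))

  # age/sex grid: dominance holds in every synthetic subgroup
  for (age in c(70, 78)) {
    for (sex_adj in c(0.8, 1.25)) {
      lt <- make_life_table(68, 98, 5, 0.0127, 1.6, sex_adjustment = sex_adj)
      res <- subgroup_run(cfg, life_table_override = lt, start_age_override = age)
      expect_lt(res$incr_cost, 0)
      expect_gt(res$incr_qaly, 0)
    }
  }
})
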