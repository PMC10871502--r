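test_that("beta moment matching solves the moment equations", {
  mm <- beta_from_moments(0.95, 0.005)
  expect_equal(mm$shape1, 1804.05, tolerance = 1e-10)
  expect_equal(mm$shape2, 94.95, tolerance = 1e-10)
  # analytic round trip for a spread of (mean, sd) pairs
  for (m in c(0.1, 0.21, 0.42, 0.67, 0.95)) {
    for (s in c(0.005, 0.02, 0.08)) {
      p <- beta_from_moments(m, s)
      expect_equal(p$shape1 / (p$shape1 + p$shape2), m, tolerance = 1e-10)
      v <- p$shape1 * p$shape2 / ((p$shape1 + p$shape2)^2 * (p$shape1 + p$shape2 + 1))
      expect_equal(sqrt(v), s, tolerance = 1e-10)
    }
  }
  # shrinking sd concentrates at the mean and shapes diverge symmetrically
  tight <- beta_from_moments(0.5, 1e-6)
  expect_equal(tight$shape1, tight$shape2)
  expect_gt(tight$shape1, 1e10)
  expect_error(beta_from_moments(0.5, 0.6, "p_bad"), "p_bad")
  expect_error(beta_from_moments(1.2, 0.1), "mean")
})

test_that("sampled beta parameters reproduce published means", {
  set.seed(101)
  mm <- beta_from_moments(0.21, 0.011)
  x <- rbeta(1e5, mm$shape1, mm$shape2)
  expect_lt(abs(mean(x) - 0.21), 3 * 0.011 / sqrt(1e5))
})

test_that("gamma moment matching is exact and recovers the exponential", {
  mm <- gamma_from_moments(18180, 2272)
  expect_equal(mm$shape, 64.02817211, tolerance = 1e-8)
  expect_equal(mm$scale, 283.9375138, tolerance = 1e-8)
  expect_equal(mm$shape * mm$scale, 18180, tolerance = 1e-12)
  expect_equal(sqrt(mm$shape) * mm$scale, 2272, tolerance = 1e-12)
  expect_equal(gamma_from_moments(500, 500)$shape, 1, tolerance = 1e-12)
  set.seed(7)
  mm <- gamma_from_moments(3678, 368)
  x <- rgamma(1e5, mm$shape, scale = mm$scale)
  expect_lt(abs(mean(x) - 3678), 3 * 368 / sqrt(1e5))
  expect_error(gamma_from_moments(-1, 1), "positive")
})

test_that("lognormal moment matching works on the natural scale", {
  mm <- lognormal_from_moments(2.37, 0.235)
  expect_equal(mm$meanlog, 0.8579979968, tolerance = 1e-8)
  expect_equal(mm$sdlog, 0.09891368346, tolerance = 1e-8)
  # analytic natural-scale moments of the matched distribution
  expect_equal(exp(mm$meanlog + mm$sdlog^2 / 2), 2.37, tolerance = 1e-12)
  expect_equal(sqrt((exp(mm$sdlog^2) - 1) * exp(2 * mm$meanlog + mm$sdlog^2)),
               0.235, tolerance = 1e-12)
  set.seed(11)
  mm <- lognormal_from_moments(1.71, 0.170)
  x <- rlnorm(1e5, mm$meanlog, mm$sdlog)
  expect_lt(abs(mean(x) - 1.71), 3 * 0.170 / sqrt(1e5))
  # vanishing sd degenerates at the mean
  tiny <- lognormal_from_moments(1, 1e-9)
  expect_equal(exp(tiny$meanlog), 1, tolerance = 1e-6)
  expect_lt(tiny$sdlog, 1e-8)
  expect_error(lognormal_from_moments(0, 1), "positive")
})

test_that("dirichlet concentrations scale probabilities by the effective sample size", {
  probs <- c(0.106, 0.185, 0.329, 0.219, 0.106, 0.017, 0.038)
  a <- dirichlet_alphas(probs, 579)
  expect_equal(a[1:2], c(61.374, 107.115), tolerance = 1e-10)
  expect_equal(sum(a), 579, tolerance = 1e-10)
  expect_equal(dirichlet_alphas(rep(1 / 7, 7), 100), rep(100 / 7, 7))
  expect_error(dirichlet_alphas(c(0.5, 0.6), 10), "sum to 1")
  expect_error(dirichlet_alphas(probs, -1), "positive")
})

test_that("spec sampling honors supports, truncation and structural zeros", {
  set.seed(3)
  hr <- dist_spec("hr", 1, "lognormal", sd = 0.05, truncate_low = 1)
  x <- sample_spec(hr, 5000)
  expect_true(all(x >= 1))
  w <- dist_spec("weight", 75, "beta", sd = 12.5, scale_low = 50, scale_high = 120)
  y <- sample_spec(w, 20000)
  expect_true(all(y >= 50 & y <= 120))
  expect_lt(abs(mean(y) - 75), 3 * 12.5 / sqrt(20000))
  expect_equal(sample_spec(dist_spec("fx", 0.3, "fixed"), 4), rep(0.3, 4))
  # Dirichlet structural zero: a zero-probability category is never drawn
  set.seed(4)
  z <- tirocea:::rdirichlet(500, c(2, 0, 5))
  expect_true(all(z[, 2] == 0))
  expect_equal(rowSums(z), rep(1, 500))
})
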