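#' Generate a synthetic life table
#'
#' Gompertz-like banded mortality: band `k` (0-based) has annual death
#' probability `min(1, base * growth^k * sex_adjustment)`. Used for subgroup
#' analysis and as the documented stand-in for the unavailable US background
#' mortality table.
#'
#' @param start_age,end_age Coverage in years.
#' @param band_width Band width in years.
#' @param base_annual_prob Annual death probability of the first band.
#' @param growth_per_band Multiplicative escalation per band, `>= 1`.
#' @param sex_adjustment Multiplicative adjustment (e.g. <1 for women).
#' @return A [life_table()].
#' @export
make_life_table <- function(start_age, end_age, band_width = 5,
                            base_annual_prob = 0.013, growth_per_band = 1.62,
                            sex_adjustment = 1) {
  if (end_age <= start_age || band_width <= 0) {
    stop("make_life_table: degenerate age range", call. = FALSE)
  }
  if (growth_per_band < 1) stop("make_life_table: growth_per_band must be >= 1", call. = FALSE)
  starts <- seq(start_age, end_age, by = band_width)
  p <- base_annual_prob * growth_per_band^(seq_along(starts) - 1) * sex_adjustment
  if (any(p > 1)) {
    warning("make_life_table: probabilities capped at 1 in the oldest bands")
    p <- pmin(1, p)
  }
  life_table(starts, starts + band_width - 1, p)
}

#' Synthetic placeholder US life table
#'
#' The published US background-mortality table is supplementary material that
#' is not publicly printed, so the US scenario ships this SYNTHETIC stand-in:
#' 5-year bands from age 68, base annual probability 0.013, escalating 1.62x
#' per band (bracketing the growth pattern of the printed Chinese bands). It
#' is not source data; US absolute results carry a wider tolerance for exactly
#' this reason, and any user-supplied [life_table()] can replace it via
#' [subgroup_run()].
#'
#' @return A [life_table()].
#' @export
us_placeholder_life_table <- function() {
  make_life_table(68, 98, band_width = 5, base_annual_prob = 0.013,
                  growth_per_band = 1.62, sex_adjustment = 1)
}

#' Null scenario with identical arms
#'
#' A China-layout scenario in which both arms share the aspirin month-3
#' distribution, sICH is impossible in both arms, and drug/infusion prices are
#' zero, so every increment is exactly zero by symmetry. Used to certify that
#' nothing arm-specific leaks through the pipeline.
#'
#' @return A `scenario_config`.
#' @export
make_null_scenario <- function() {
  cfg <- china_base()
  cfg$mrs_month3$tirofiban <- cfg$mrs_month3$aspirin
  cfg$params$p_sich_tirofiban <- dist_spec("p_sich_tirofiban", 0, "fixed")
  cfg$params$drug_price_per_mg <- dist_spec("drug_price_per_mg", 0, "fixed")
  cfg$params$infusion_first_hour <- dist_spec("infusion_first_hour", 0, "fixed")
  cfg$params$infusion_additional_hour <- dist_spec("infusion_additional_hour", 0, "fixed")
  validate_scenario(cfg)
}

#' Collapsed-state scenario for exhaustive-path verification
#'
#' A reduced analogue of the model with `n_states` total health states (last
#' absorbing) and a short horizon of `n_cycles` Markov cycles, small enough
#' that total cost and QALY can be recomputed by enumerating every event path.
#' Parameters are fixed, deterministic, and mildly jittered by `seed` so
#' repeated property tests explore different valid instances.
#'
#' @param n_states Total states including death, 2..4.
#' @param n_cycles Markov cycles after the acute quarter, 2..6.
#' @param seed Determines the jitter; same seed, same scenario.
#' @return A `scenario_config` with `n_states` states.
#' @export
make_oracle_scenario <- function(n_states = 3, n_cycles = 4, seed = 1) {
  if (n_states < 2 || n_states > 4) stop("make_oracle_scenario: n_states must be 2..4", call. = FALSE)
  if (n_cycles < 2 || n_cycles > 6) stop("make_oracle_scenario: n_cycles must be 2..6", call. = FALSE)
  set.seed(seed)
  A <- n_states - 1
  states <- c(paste0("state", seq_len(A) - 1), "dead")
  u_base <- sort(stats::runif(A, 0.2, 0.9), decreasing = TRUE)
  hr_base <- cumsum(c(1, stats::runif(A - 1, 0, 0.6)))
  params <- c(
    list(dist_spec("p_sich_tirofiban", 0.01, "beta", sd = 0.003),
         dist_spec("p_sich_aspirin", 0, "fixed"),
         dist_spec("p_recurrent_annual", round(stats::runif(1, 0.05, 0.2), 3), "beta", sd = 0.01),
         dist_spec("p_death_after_recurrence", 0.25, "beta", sd = 0.02),
         dist_spec("u_recurrence", 0.35, "beta", sd = 0.05),
         dist_spec("du_sich", 0.3, "beta", sd = 0.04),
         dist_spec("discount_rate", 0.05, "fixed", low = 0, high = 0.08),
         dist_spec("drug_price_per_mg", 10, "gamma", sd = 1),
         dist_spec("weight_kg", 75, "beta", sd = 10, low = 50, high = 100,
                   scale_low = 50, scale_high = 100),
         dist_spec("infusion_first_hour", 20, "gamma", sd = 2),
         dist_spec("infusion_additional_hour", 2, "gamma", sd = 0.2),
         dist_spec("acute_alive", 1000, "gamma", sd = 100),
         dist_spec("acute_death", 1500, "gamma", sd = 150),
         dist_spec("cost_sich", 500, "gamma", sd = 50),
         dist_spec("cost_recurrent", 2000, "gamma", sd = 200)),
    lapply(seq_len(A), function(i) {
      dist_spec(paste0("hr_s", i - 1), hr_base[i], "lognormal", sd = 0.1, truncate_low = 1)
    }),
    lapply(seq_len(A), function(i) {
      dist_spec(paste0("u_s", i - 1), round(u_base[i], 3), "beta", sd = 0.02)
    }),
    lapply(seq_len(A), function(i) {
      dist_spec(paste0("posthosp_s", i - 1), round(500 * i * stats::runif(1, 0.8, 1.2)), "gamma",
                sd = 50)
    }))
  names(params) <- vapply(params, function(p) p$name, character(1))
  m <- stats::runif(n_states, 0.2, 1)
  m <- m / sum(m)
  scenario_config(
    country = "oracle", currency = "XXX", start_age = 70,
    horizon_years = (n_cycles + 1) * 0.25, cycle_length_years = 0.25, wtp = 1e4,
    mrs_month3 = list(tirofiban = m, aspirin = rev(m) / sum(m)),
    params = params, state_names = states,
    hr_params = paste0("hr_s", seq_len(A) - 1),
    utility_params = paste0("u_s", seq_len(A) - 1),
    acute_map = c(list(acute_alive = seq_len(A)), list(acute_death = n_states)),
    posthosp = list(period = "quarterly",
                    map = as.list(stats::setNames(seq_len(A), paste0("posthosp_s", seq_len(A) - 1)))),
    life_table = life_table(70, 120, round(stats::runif(1, 0.02, 0.1), 3)),
    psa_ess = 100)
}
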