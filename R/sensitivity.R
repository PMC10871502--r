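#' Parameters eligible for one-way sensitivity analysis
#'
#' All parameters carrying a published range. The month-3 mRS distributions
#' have no printed ranges and are varied only in the PSA.
#'
#' @param cfg A `scenario_config`.
#' @return Character vector of parameter names.
#' @export
ranged_parameters <- function(cfg) {
  names(cfg$params)[vapply(cfg$params, function(p) is.finite(p$low) && is.finite(p$high),
                           logical(1))]
}

#' One-way sensitivity analysis for a single parameter
#'
#' Runs the full model twice with the parameter pinned at each range endpoint
#' (everything else at base), recording the ICER and the incremental net
#' monetary benefit at the scenario's WTP. The span is measured on the
#' incremental-NMB scale, which stays ordered when ICERs go negative.
#'
#' @param cfg A `scenario_config`.
#' @param parameter Name of a ranged parameter (see [ranged_parameters()]).
#' @return One-row data frame: parameter, endpoints, ICER and incremental NMB
#'   at each endpoint, and the NMB span.
#' @export
one_way <- function(cfg, parameter) {
  if (!parameter %in% names(cfg$params)) {
    stop(sprintf("one_way: unknown parameter '%s'", parameter), call. = FALSE)
  }
  spec <- cfg$params[[parameter]]
  if (!is.finite(spec$low) || !is.finite(spec$high)) {
    stop(sprintf("one_way: parameter '%s' has no published range", parameter), call. = FALSE)
  }
  run_at <- function(v) {
    vals <- base_values(cfg)
    vals[[parameter]] <- v
    res <- run_scenario(cfg, vals)
    c(icer = res$icer$ratio, dnmb = nmb(res$incr_cost, res$incr_qaly, cfg$wtp))
  }
  lo <- run_at(spec$low)
  hi <- run_at(spec$high)
  data.frame(parameter = parameter, low_input = spec$low, high_input = spec$high,
             icer_low = unname(lo["icer"]), icer_high = unname(hi["icer"]),
             dnmb_low = unname(lo["dnmb"]), dnmb_high = unname(hi["dnmb"]),
             span = abs(unname(hi["dnmb"]) - unname(lo["dnmb"])))
}

#' Tornado table
#'
#' One-way analysis over every ranged parameter, sorted by descending
#' incremental-NMB span (name as tie-break), the ordering a tornado diagram
#' plots.
#'
#' @param cfg A `scenario_config`.
#' @return Data frame of [one_way()] records, widest span first.
#' @export
tornado <- function(cfg) {
  recs <- do.call(rbind, lapply(sort(ranged_parameters(cfg)), one_way, cfg = cfg))
  recs <- recs[order(-recs$span, recs$parameter), ]
  rownames(recs) <- NULL
  recs
}

# Stable per-parameter seed stream: a polynomial hash of the name mixed with
# the master seed, so adding a parameter never perturbs the others' draws.
param_seed <- function(master_seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (master_seed %% 2147483647) * 48271) %% 2147483647)
}

draw_param <- function(spec, n, master_seed) {
  set.seed(param_seed(master_seed, spec$name))
  sample_spec(spec, n)
}

draw_mrs <- function(probs, ess, n, master_seed, stream) {
  alphas <- dirichlet_alphas(as.numeric(probs), ess)
  g <- matrix(0, n, length(alphas))
  for (j in seq_along(alphas)) {
    if (alphas[j] <= 0) next
    set.seed(param_seed(master_seed, sprintf("%s[%d]", stream, j)))
    g[, j] <- stats::rgamma(n, shape = alphas[j], rate = 1)
  }
  g / rowSums(g)
}

#' Probabilistic sensitivity analysis
#'
#' Draws every stochastic parameter from its moment-matched family (gamma for
#' costs, beta for probabilities/utilities/weight, natural-scale lognormal
#' truncated at 1 for hazard ratios, Dirichlet for each arm's month-3 mRS
#' distribution) and reruns the full model per draw. Parameters shared by the
#' arms (costs, utilities, hazard ratios, recurrence) use one common draw;
#' arm-specific inputs are drawn per arm. `fixed`-family parameters (the
#' discount rate, the aspirin sICH probability) stay at base. Each parameter
#' has its own seed substream derived from `seed`, so runs are reproducible
#' and insensitive to parameter ordering.
#'
#' @param cfg A `scenario_config`.
#' @param n_iterations Number of draws (the reference analysis uses 10,000).
#' @param seed Master seed.
#' @param share_arm_draws Use the tirofiban substream for both arms' Dirichlet
#'   draws (common random numbers; used by null-scenario symmetry checks).
#' @return A `psa_result`: `samples` data frame (per-arm cost/QALY, increments,
#'   quadrant), the parameter draw matrix, `n`, and `seed`.
#' @export
run_psa <- function(cfg, n_iterations = 10000, seed = 1, share_arm_draws = FALSE) {
  stopifnot(n_iterations >= 1)
  validate_scenario(cfg)
  n <- n_iterations

  sampled <- names(cfg$params)[vapply(cfg$params, function(p) p$family != "fixed", logical(1))]
  draws <- matrix(rep(base_values(cfg), each = n), nrow = n,
                  dimnames = list(NULL, names(cfg$params)))
  for (nm in sampled) draws[, nm] <- draw_param(cfg$params[[nm]], n, seed)

  mrs_t <- draw_mrs(cfg$mrs_month3$tirofiban, cfg$psa_ess, n, seed, "mrs_tirofiban")
  mrs_a <- if (share_arm_draws) {
    draw_mrs(cfg$mrs_month3$aspirin, cfg$psa_ess, n, seed, "mrs_tirofiban")
  } else {
    draw_mrs(cfg$mrs_month3$aspirin, cfg$psa_ess, n, seed, "mrs_aspirin")
  }

  cost_t <- qaly_t <- cost_a <- qaly_a <- numeric(n)
  for (i in seq_len(n)) {
    vals <- draws[i, ]
    prep <- engine_prep(cfg, vals)
    ac_t <- acute_phase(cfg, "tirofiban", vals, mrs_override = mrs_t[i, ])
    mk_t <- engine_run(mrs_t[i, ], prep)
    ac_a <- acute_phase(cfg, "aspirin", vals, mrs_override = mrs_a[i, ])
    mk_a <- engine_run(mrs_a[i, ], prep)
    cost_t[i] <- ac_t$cost + mk_t$cost
    qaly_t[i] <- ac_t$qaly + mk_t$qaly
    cost_a[i] <- ac_a$cost + mk_a$cost
    qaly_a[i] <- ac_a$qaly + mk_a$qaly
  }
  incr_cost <- cost_t - cost_a
  incr_qaly <- qaly_t - qaly_a
  quadrant <- ifelse(incr_qaly > 0 & incr_cost >= 0, "I",
              ifelse(incr_qaly <= 0 & incr_cost >= 0, "II",
              ifelse(incr_qaly <= 0, "III", "IV")))
  samples <- data.frame(draw = seq_len(n), cost_tirofiban = cost_t,
                        qaly_tirofiban = qaly_t, cost_aspirin = cost_a,
                        qaly_aspirin = qaly_a, incr_cost = incr_cost,
                        incr_qaly = incr_qaly, quadrant = quadrant)
  structure(list(samples = samples, param_draws = draws, n = n, seed = seed,
                 country = cfg$country, wtp = cfg$wtp),
            class = "psa_result")
}

#' CE-plane quadrant fractions of a PSA
#'
#' @param psa A `psa_result`.
#' @return Named numeric vector of the four quadrant fractions (sums to 1).
#'   Quadrant IV (cost-saving with a QALY gain) is where a dominant
#'   intervention's draws land.
#' @export
psa_quadrants <- function(psa) {
  stopifnot(inherits(psa, "psa_result"))
  tab <- table(factor(psa$samples$quadrant, levels = c("I", "II", "III", "IV")))
  stats::setNames(as.numeric(tab) / psa$n, c("I", "II", "III", "IV"))
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws with positive incremental net monetary benefit at each
#' willingness-to-pay value. At WTP = 0 this is the fraction of cost-saving
#' draws.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid WTP values; must include 0.
#' @return Data frame with `wtp` and `acceptability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 2e5, by = 5000)) {
  stopifnot(inherits(psa, "psa_result"))
  if (psa$n == 0) stop("ceac: empty sample set", call. = FALSE)
  if (!0 %in% wtp_grid) stop("ceac: wtp_grid must include 0", call. = FALSE)
  acc <- vapply(wtp_grid, function(w) {
    mean(psa$samples$incr_qaly * w - psa$samples$incr_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, acceptability = acc)
}

#' @export
print.psa_result <- function(x, ...) {
  q <- psa_quadrants(x)
  cat(sprintf("<psa_result %s: %d draws, seed %d>\n", x$country, x$n, x$seed))
  cat(sprintf("  quadrant IV (dominant) %.1f%%; acceptability at WTP 0: %.1f%%\n",
              100 * q[["IV"]], 100 * mean(x$samples$incr_cost < 0)))
  invisible(x)
}

#' Base-case run under substituted background mortality
#'
#' Subgroup analysis by age/sex proceeds by swapping in the subgroup's life
#' table (and optionally its starting age) and rerunning the base case.
#'
#' @param cfg A `scenario_config`.
#' @param life_table_override A [life_table()] for the subgroup.
#' @param start_age_override Optional starting age.
#' @return A `cea_result`.
#' @export
subgroup_run <- function(cfg, life_table_override = NULL, start_age_override = NULL) {
  if (!is.null(life_table_override)) {
    stopifnot(inherits(life_table_override, "life_table"))
    cfg$life_table <- life_table_override
  }
  if (!is.null(start_age_override)) cfg$start_age <- start_age_override
  validate_scenario(cfg)
  run_scenario(cfg)
}
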