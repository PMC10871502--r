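#' Incremental cost-effectiveness ratio
#'
#' Ratio of incremental cost to incremental effectiveness (tirofiban minus
#' aspirin), with a dominance classification: `"dominant"` when the
#' intervention saves money and gains QALYs (cost-effectiveness plane quadrant
#' IV), `"dominated"` in the opposite corner (quadrant II). Negative ratios are
#' reported alongside the flag, matching how dominant results are usually
#' printed, but are not ordered meaningfully; comparisons should use net
#' monetary benefit.
#'
#' @param incr_cost Incremental cost.
#' @param incr_qaly Incremental effectiveness (QALYs).
#' @return List with `ratio` (NA when `incr_qaly` is 0), `flag` (one of
#'   `"dominant"`, `"dominated"`, `"ratio"`, `"undefined"`), and `quadrant`
#'   (`"I"`..`"IV"`).
#' @export
icer <- function(incr_cost, incr_qaly) {
  quadrant <- if (incr_qaly > 0 && incr_cost >= 0) "I"
    else if (incr_qaly <= 0 && incr_cost >= 0) "II"
    else if (incr_qaly <= 0 && incr_cost < 0) "III"
    else "IV"
  if (incr_qaly == 0) {
    return(list(ratio = NA_real_, flag = "undefined", quadrant = quadrant))
  }
  flag <- if (incr_cost < 0 && incr_qaly > 0) "dominant"
    else if (incr_cost > 0 && incr_qaly < 0) "dominated"
    else "ratio"
  list(ratio = incr_cost / incr_qaly, flag = flag, quadrant = quadrant)
}

#' Net monetary benefit
#'
#' `qaly * wtp - cost`: positive differences in NMB identify the cost-effective
#' strategy without the sign ambiguities of negative ICERs.
#'
#' @param cost Total cost.
#' @param qaly Total effectiveness in QALYs.
#' @param wtp Willingness-to-pay per QALY, `>= 0`.
#' @return Net monetary benefit.
#' @export
nmb <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) stop("nmb: wtp must be nonnegative", call. = FALSE)
  qaly * wtp - cost
}

#' Is the intervention cost-effective at a threshold?
#'
#' TRUE iff the incremental net monetary benefit at `wtp` is positive, which
#' equals "dominant, or ICER defined and below the threshold with a QALY gain"
#' while avoiding negative-ICER ambiguity.
#'
#' @param incr_cost,incr_qaly Increments (intervention minus comparator).
#' @param wtp Willingness-to-pay per QALY.
#' @return Logical.
#' @export
decide_cost_effective <- function(incr_cost, incr_qaly, wtp) {
  if (any(wtp < 0)) stop("decide_cost_effective: wtp must be nonnegative", call. = FALSE)
  (incr_qaly * wtp - incr_cost) > 0
}

#' Run the full hybrid model for one scenario
#'
#' Decision-tree acute quarter plus Markov cycling for both arms, combined into
#' the comparative cost-effectiveness summary.
#'
#' @param cfg A `scenario_config`.
#' @param values Parameter values (default the base case).
#' @param mrs_tirofiban,mrs_aspirin Month-3 distribution overrides (used by the
#'   PSA).
#' @return A `cea_result`: `arms` data frame (arm, cost, qaly, nmb at the
#'   scenario WTP), increments, `icer` classification, and the WTP used.
#' @export
run_scenario <- function(cfg, values = base_values(cfg),
                         mrs_tirofiban = NULL, mrs_aspirin = NULL) {
  prep <- engine_prep(cfg, values)
  one_arm <- function(arm, override) {
    ac <- acute_phase(cfg, arm, values, mrs_override = override)
    mk <- engine_run(ac$mrs_month3, prep)
    c(cost = ac$cost + mk$cost, qaly = ac$qaly + mk$qaly)
  }
  t <- one_arm("tirofiban", mrs_tirofiban)
  a <- one_arm("aspirin", mrs_aspirin)
  incr_cost <- unname(t["cost"] - a["cost"])
  incr_qaly <- unname(t["qaly"] - a["qaly"])
  arms <- data.frame(arm = c("aspirin", "tirofiban"),
                     cost = c(a["cost"], t["cost"]),
                     qaly = c(a["qaly"], t["qaly"]))
  arms$nmb <- nmb(arms$cost, arms$qaly, cfg$wtp)
  structure(list(country = cfg$country, currency = cfg$currency, arms = arms,
                 incr_cost = incr_cost, incr_qaly = incr_qaly,
                 icer = icer(incr_cost, incr_qaly), wtp = cfg$wtp,
                 cost_effective = decide_cost_effective(incr_cost, incr_qaly, cfg$wtp)),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result %s (%s), WTP %s/QALY>\n", x$country, x$currency,
              format(x$wtp, big.mark = ",")))
  arms <- x$arms
  arms$cost <- round(arms$cost)
  arms$qaly <- round(arms$qaly, 3)
  arms$nmb <- round(arms$nmb)
  print(arms, row.names = FALSE)
  ratio <- if (is.na(x$icer$ratio)) "undefined" else format(round(x$icer$ratio), big.mark = ",")
  cat(sprintf("  incr cost %s, incr QALY %s, ICER %s per QALY (%s, quadrant %s)\n",
              format(round(x$incr_cost), big.mark = ","), round(x$incr_qaly, 4),
              ratio, x$icer$flag, x$icer$quadrant))
  invisible(x)
}

#' Export a cost-effectiveness summary table
#'
#' Two-row table in the customary layout: per-arm totals, increments, ICER.
#'
#' @param result A `cea_result`.
#' @return A data frame.
#' @export
cea_table <- function(result) {
  stopifnot(inherits(result, "cea_result"))
  data.frame(
    arm = result$arms$arm,
    total_cost = result$arms$cost,
    total_eff = result$arms$qaly,
    incr_cost = c(NA, result$incr_cost),
    incr_eff = c(NA, result$incr_qaly),
    icer = c(NA, result$icer$ratio),
    currency = result$currency)
}
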