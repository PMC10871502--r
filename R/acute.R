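#' Tirofiban acquisition cost for one treatment course
#'
#' Total dose = weight x (loading rate x loading minutes + maintenance rate x
#' maintenance hours x 60) / 1000 mg, at the default regimen 0.4 ug/kg/min for
#' 30 min then 0.1 ug/kg/min for 48 h (22.5 mg for a 75 kg patient).
#'
#' @param weight_kg Patient weight, kg.
#' @param price_per_mg Drug price per mg.
#' @param loading_rate_ug_kg_min,loading_minutes Loading infusion rate and
#'   duration.
#' @param maintenance_rate_ug_kg_min,maintenance_hours Maintenance infusion
#'   rate and duration.
#' @return Drug cost.
#' @export
tirofiban_drug_cost <- function(weight_kg, price_per_mg,
                                loading_rate_ug_kg_min = 0.4, loading_minutes = 30,
                                maintenance_rate_ug_kg_min = 0.1, maintenance_hours = 48) {
  args <- c(weight_kg, price_per_mg, loading_rate_ug_kg_min, loading_minutes,
            maintenance_rate_ug_kg_min, maintenance_hours)
  if (any(!is.finite(args)) || any(args < 0)) {
    stop("tirofiban_drug_cost: all inputs must be nonnegative", call. = FALSE)
  }
  mg <- weight_kg * (loading_rate_ug_kg_min * loading_minutes +
                     maintenance_rate_ug_kg_min * maintenance_hours * 60) / 1000
  mg * price_per_mg
}

#' Intravenous infusion administration fee
#'
#' First hour billed at the first-hour fee; each additional (started) hour at
#' the additional-hour fee.
#'
#' @param total_hours Infusion duration, hours.
#' @param first_hour_cost,additional_hour_cost Fee schedule.
#' @return Infusion fee (0 for a zero-length infusion).
#' @export
infusion_cost <- function(total_hours, first_hour_cost, additional_hour_cost) {
  if (!is.finite(total_hours) || total_hours < 0) {
    stop("infusion_cost: total_hours must be nonnegative", call. = FALSE)
  }
  if (total_hours == 0) return(0)
  first_hour_cost + additional_hour_cost * ceiling(max(total_hours - 1, 0))
}

#' Expected acute-phase hospitalisation cost
#'
#' Expectation of the grouped acute-care cost under a month-3 disability
#' distribution. China groups states as mRS 0-1 / 2-5 / death; the US as
#' mRS 0-2 / 3-5 / death; the grouping travels with the scenario.
#'
#' @param mrs_month3 Probability vector over the health states.
#' @param acute_costs Named vector of group costs.
#' @param acute_map Named list mapping cost names to the state indices they
#'   cover (must partition the states).
#' @return Expected acute cost.
#' @export
acute_stroke_cost <- function(mrs_month3, acute_costs, acute_map) {
  if (!setequal(names(acute_costs), names(acute_map))) {
    stop("acute_stroke_cost: cost table and grouping name mismatch", call. = FALSE)
  }
  covered <- as.integer(sort(unlist(acute_map, use.names = FALSE)))
  if (!identical(covered, seq_along(mrs_month3))) {
    stop("acute_stroke_cost: grouping does not partition the states", call. = FALSE)
  }
  sum(vapply(names(acute_map),
             function(g) sum(mrs_month3[acute_map[[g]]]) * acute_costs[[g]],
             numeric(1)))
}

#' Expected cost and QALY loss from symptomatic intracranial hemorrhage
#'
#' @param p_sich Probability of sICH in the arm (0 for aspirin).
#' @param cost_sich Cost per event.
#' @param disutility_sich Utility decrement while affected.
#' @param exposure_years Duration the decrement applies (default one acute
#'   quarter).
#' @return List with `cost` and `qaly_loss`.
#' @export
expected_sich_burden <- function(p_sich, cost_sich, disutility_sich,
                                 exposure_years = 0.25) {
  if (!is.finite(p_sich) || p_sich < 0 || p_sich > 1) {
    stop("expected_sich_burden: p_sich must lie in [0, 1]", call. = FALSE)
  }
  list(cost = p_sich * cost_sich,
       qaly_loss = p_sich * disutility_sich * exposure_years)
}

#' Acute-quarter QALY
#'
#' One quarter of life weighted by the expected month-3 utility:
#' `0.25 * sum(p_i * u_i)` (death carries utility 0).
#'
#' @param mrs_month3 Probability vector over the health states.
#' @param utilities Utility per living state (death excluded).
#' @param cycle_length_years Quarter length in years.
#' @return QALYs accrued over the acute quarter.
#' @export
acute_qaly <- function(mrs_month3, utilities, cycle_length_years = 0.25) {
  n_alive <- length(mrs_month3) - 1
  stopifnot(length(utilities) == n_alive)
  cycle_length_years * sum(mrs_month3[seq_len(n_alive)] * utilities)
}

#' Run the decision-tree (acute) stage for one arm
#'
#' Combines drug and infusion costs (tirofiban arm only, unless the
#' `infusion_in_aspirin` toggle is set), the expected acute hospitalisation
#' cost, and the sICH cost/disutility, and returns the month-3 distribution the
#' Markov stage starts from. Acute-phase accruals are not discounted (they fall
#' in year 0).
#'
#' @param cfg A `scenario_config`.
#' @param arm `"tirofiban"` or `"aspirin"`.
#' @param values Parameter values (default the base case); see [base_values()].
#' @param mrs_override Replacement month-3 distribution (used by the PSA's
#'   Dirichlet draws).
#' @return List with `arm`, `cost`, `qaly`, `mrs_month3`, and a `components`
#'   breakdown.
#' @export
acute_phase <- function(cfg, arm = c("tirofiban", "aspirin"),
                        values = base_values(cfg), mrs_override = NULL) {
  arm <- match.arg(arm)
  m <- if (is.null(mrs_override)) as.numeric(cfg$mrs_month3[[arm]]) else as.numeric(mrs_override)
  reg <- cfg$regimen
  infusion_hours <- reg$loading_minutes / 60 + reg$maintenance_hours

  drug <- if (arm == "tirofiban") {
    tirofiban_drug_cost(values[["weight_kg"]], values[["drug_price_per_mg"]],
                        reg$loading_rate_ug_kg_min, reg$loading_minutes,
                        reg$maintenance_rate_ug_kg_min, reg$maintenance_hours)
  } else 0
  infusion <- if (arm == "tirofiban" || isTRUE(cfg$toggles$infusion_in_aspirin)) {
    infusion_cost(infusion_hours, values[["infusion_first_hour"]],
                  values[["infusion_additional_hour"]])
  } else 0

  acute_costs <- values[names(cfg$acute_map)]
  care <- acute_stroke_cost(m, acute_costs, cfg$acute_map)

  p_sich <- values[[paste0("p_sich_", arm)]]
  sich <- expected_sich_burden(p_sich, values[["cost_sich"]], values[["du_sich"]],
                               cfg$sich_exposure_years)

  u <- values[cfg$utility_params]
  qaly0 <- acute_qaly(m, u, cfg$cycle_length_years)

  list(arm = arm,
       cost = drug + infusion + care + sich$cost,
       qaly = qaly0 - sich$qaly_loss,
       mrs_month3 = m,
       components = list(drug = drug, infusion = infusion, acute_care = care,
                         sich_cost = sich$cost, base_qaly = qaly0,
                         sich_qaly_loss = sich$qaly_loss))
}
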