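#' Assemble a scenario configuration
#'
#' A scenario is the complete, validated parameter set for one country-specific
#' model run: month-3 mRS distributions per arm, every sampled or ranged
#' parameter as a [dist_spec()], the life table, the infusion regimen, and the
#' engine toggles for conventions the source material leaves open.
#'
#' Most users want [load_scenario()] with one of the built-ins; this
#' constructor is for fully custom scenarios (and the collapsed-state test
#' scenarios, which use fewer health states).
#'
#' @param country Scenario label, e.g. `"china"` or `"us"`.
#' @param currency Currency label (never converted, only printed).
#' @param start_age Cohort age at the index stroke, years.
#' @param horizon_years Model horizon, years; must be a multiple of the cycle
#'   length.
#' @param cycle_length_years Markov cycle length in years (0.25 = 3 months).
#' @param wtp Willingness-to-pay threshold per QALY.
#' @param mrs_month3 Named list with elements `tirofiban` and `aspirin`, each a
#'   probability vector over the health states (see [mrs_distribution()]).
#' @param params Named list of [dist_spec()] objects. Required names are given
#'   in the vignette; the builders [china_base()] and [us_base()] are the
#'   reference layout.
#' @param state_names Health-state labels; the last state is absorbing death.
#' @param hr_params,utility_params Parameter names (in `params`) holding the
#'   death hazard ratio and the utility for each living state.
#' @param acute_map Named list mapping acute-phase cost parameter names to the
#'   1-based state indices they cover (death included).
#' @param posthosp Post-hospitalisation cost layout: `list(period, map)` where
#'   `period` is `"annual"` (cost divided across cycles) or `"quarterly"`
#'   (charged per cycle as-is) and `map` maps cost parameter names to living
#'   state indices.
#' @param life_table A [life_table()].
#' @param psa_ess Dirichlet effective sample size for the month-3
#'   distributions (default 579, about one trial arm).
#' @param regimen Tirofiban infusion regimen: loading rate (ug/kg/min), loading
#'   minutes, maintenance rate, maintenance hours.
#' @param sich_exposure_years How long the sICH disutility applies (default the
#'   acute quarter).
#' @param toggles Engine conventions; see Details.
#'
#' @details The toggles (all documented in the methods vignette) are:
#' `half_cycle` (FALSE: accrue on end-of-cycle membership),
#' `recurrence_includes_source` (TRUE: recurrence survivors redistribute over
#' their own and worse states), `infusion_in_aspirin` (FALSE: infusion fees
#' charged to the tirofiban arm only), `recurrence_utility_mode`
#' (`"absolute"`: the recurrence utility replaces the state utility during the
#' recurrence cycle; `"decrement"`: it is subtracted), `mortality_conversion`
#' (`"annual_per_cycle"`: the annual background death probability is applied
#' per 3-month cycle, which reproduces the published totals; `"quarterly"`:
#' the annual-rate-to-cycle-probability formula), and `discount_costs` /
#' `discount_effects` (reproduction defaults FALSE / TRUE).
#'
#' @return A validated object of class `scenario_config`.
#' @export
scenario_config <- function(country, currency, start_age, horizon_years,
                            cycle_length_years, wtp, mrs_month3, params,
                            state_names = paste0("mrs", 0:6),
                            hr_params = paste0("hr_mrs", 0:5),
                            utility_params = paste0("u_mrs", 0:5),
                            acute_map, posthosp, life_table,
                            psa_ess = 579,
                            regimen = list(loading_rate_ug_kg_min = 0.4,
                                           loading_minutes = 30,
                                           maintenance_rate_ug_kg_min = 0.1,
                                           maintenance_hours = 48),
                            sich_exposure_years = 0.25,
                            toggles = default_toggles()) {
  cfg <- structure(
    list(country = country, currency = currency, start_age = start_age,
         horizon_years = horizon_years, cycle_length_years = cycle_length_years,
         wtp = wtp, mrs_month3 = mrs_month3, params = params,
         state_names = state_names, hr_params = hr_params,
         utility_params = utility_params, acute_map = acute_map,
         posthosp = posthosp, life_table = life_table, psa_ess = psa_ess,
         regimen = regimen, sich_exposure_years = sich_exposure_years,
         toggles = utils::modifyList(default_toggles(), toggles)),
    class = "scenario_config")
  validate_scenario(cfg)
}

#' Default engine toggles
#'
#' The documented reproduction-mode conventions; see
#' [scenario_config()] Details and the methods vignette.
#' @return Named list of toggle values.
#' @export
default_toggles <- function() {
  list(half_cycle = FALSE,
       recurrence_includes_source = TRUE,
       infusion_in_aspirin = FALSE,
       recurrence_utility_mode = "absolute",
       mortality_conversion = "annual_per_cycle",
       discount_costs = FALSE,
       discount_effects = TRUE)
}

#' Validate a scenario configuration
#'
#' Runs every structural invariant: parameter specs validate individually,
#' month-3 distributions are proper, utilities are non-increasing and hazard
#' ratios non-decreasing in disability level, the discount rate is inside its
#' admissible range, cost maps cover every state exactly once, and the horizon
#' is a whole number of cycles.
#'
#' @param cfg A `scenario_config`.
#' @return `cfg`, invisibly (errors name the offending field).
#' @export
validate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  S <- length(cfg$state_names)
  if (S < 2) stop("scenario: need at least one living state plus death", call. = FALSE)
  n_alive <- S - 1

  for (p in cfg$params) validate_dist_spec(p)
  pn <- names(cfg$params)
  required <- c("p_recurrent_annual", "p_death_after_recurrence",
                "p_sich_tirofiban", "p_sich_aspirin", "u_recurrence", "du_sich",
                "drug_price_per_mg", "weight_kg", "infusion_first_hour",
                "infusion_additional_hour", "cost_recurrent", "cost_sich",
                "discount_rate", cfg$hr_params, cfg$utility_params,
                names(cfg$acute_map), names(cfg$posthosp$map))
  missing <- setdiff(required, pn)
  if (length(missing)) {
    stop("scenario: missing parameters: ", paste(missing, collapse = ", "), call. = FALSE)
  }

  for (arm in c("tirofiban", "aspirin")) {
    m <- cfg$mrs_month3[[arm]]
    if (is.null(m)) stop(sprintf("scenario: mrs_month3$%s missing", arm), call. = FALSE)
    if (length(m) != S) {
      stop(sprintf("scenario: mrs_month3$%s has %d entries for %d states", arm, length(m), S),
           call. = FALSE)
    }
    if (any(m < 0) || abs(sum(m) - 1) > 1e-9) {
      stop(sprintf("scenario: mrs_month3$%s is not a probability distribution", arm),
           call. = FALSE)
    }
  }

  u <- vapply(cfg$params[cfg$utility_params], function(p) p$base, numeric(1))
  if (any(diff(u) > 1e-12)) {
    bad <- which(diff(u) > 1e-12)[1]
    stop(sprintf("scenario: utilities must be non-increasing in disability (%s = %g < %s = %g)",
                 cfg$utility_params[bad], u[bad], cfg$utility_params[bad + 1], u[bad + 1]),
         call. = FALSE)
  }
  hr <- vapply(cfg$params[cfg$hr_params], function(p) p$base, numeric(1))
  if (any(hr < 1)) stop("scenario: death hazard ratios must be >= 1", call. = FALSE)
  if (any(diff(hr) < -1e-12)) {
    stop("scenario: death hazard ratios must be non-decreasing in disability", call. = FALSE)
  }

  dr <- cfg$params$discount_rate$base
  if (dr < 0 || dr > 0.08) {
    stop(sprintf("scenario: discount_rate %g outside [0, 0.08]", dr), call. = FALSE)
  }

  covered <- as.integer(sort(unlist(cfg$acute_map, use.names = FALSE)))
  if (!identical(covered, seq_len(S))) {
    stop("scenario: acute_map must partition all states (death included)", call. = FALSE)
  }
  ph <- as.integer(sort(unlist(cfg$posthosp$map, use.names = FALSE)))
  if (!identical(ph, seq_len(n_alive))) {
    stop("scenario: posthosp map must partition the living states", call. = FALSE)
  }
  if (!cfg$posthosp$period %in% c("annual", "quarterly")) {
    stop("scenario: posthosp period must be 'annual' or 'quarterly'", call. = FALSE)
  }

  ncyc <- cfg$horizon_years / cfg$cycle_length_years
  if (abs(ncyc - round(ncyc)) > 1e-9) {
    stop("scenario: horizon_years must be a whole number of cycles", call. = FALSE)
  }
  if (!is.finite(cfg$psa_ess) || cfg$psa_ess <= 0) {
    stop("scenario: psa_ess must be positive", call. = FALSE)
  }
  if (cfg$start_age < cfg$life_table$age_start[1]) {
    stop("scenario: start_age below life-table coverage", call. = FALSE)
  }
  invisible(cfg)
}

#' Base-case parameter values of a scenario
#'
#' @param cfg A `scenario_config`.
#' @return Named numeric vector of every parameter's point estimate.
#' @export
base_values <- function(cfg) {
  vapply(cfg$params, function(p) p$base, numeric(1))
}

#' Built-in China scenario
#'
#' The published China parameter set: CNY costs, 5% discount rate, WTP 85,698
#' CNY/QALY, 75 kg patients, Chinese utilities and background mortality.
#'
#' @return A `scenario_config`.
#' @export
china_base <- function() {
  params <- list(
    dist_spec("p_sich_tirofiban", 0.01, "beta", sd = 0.003, low = 0, high = 0.01),
    dist_spec("p_sich_aspirin", 0, "fixed"),
    dist_spec("p_recurrent_annual", 0.017, "beta", sd = 0.001, low = 0.015, high = 0.020),
    dist_spec("p_death_after_recurrence", 0.21, "beta", sd = 0.011, low = 0.189, high = 0.232),
    dist_spec("hr_mrs0", 1, "lognormal", sd = 0.050, low = 1, high = 1.2, truncate_low = 1),
    dist_spec("hr_mrs1", 1, "lognormal", sd = 0.050, low = 1, high = 1.2, truncate_low = 1),
    dist_spec("hr_mrs2", 1.11, "lognormal", sd = 0.103, low = 1, high = 1.3, truncate_low = 1),
    dist_spec("hr_mrs3", 1.27, "lognormal", sd = 0.125, low = 1.02, high = 1.52, truncate_low = 1),
    dist_spec("hr_mrs4", 1.71, "lognormal", sd = 0.170, low = 1.37, high = 2.05, truncate_low = 1),
    dist_spec("hr_mrs5", 2.37, "lognormal", sd = 0.235, low = 1.9, high = 2.84, truncate_low = 1),
    dist_spec("u_mrs0", 0.95, "beta", sd = 0.005, low = 0.94, high = 0.96),
    dist_spec("u_mrs1", 0.89, "beta", sd = 0.023, low = 0.87, high = 0.96),
    dist_spec("u_mrs2", 0.67, "beta", sd = 0.074, low = 0.54, high = 0.83),
    dist_spec("u_mrs3", 0.44, "beta", sd = 0.079, low = 0.29, high = 0.60),
    dist_spec("u_mrs4", 0.16, "beta", sd = 0.036, low = 0.09, high = 0.23),
    dist_spec("u_mrs5", 0.10, "beta", sd = 0.054, low = 0, high = 0.21),
    dist_spec("u_recurrence", 0.42, "beta", sd = 0.153, low = 0.11, high = 0.71),
    dist_spec("du_sich", 0.38, "beta", sd = 0.041, low = 0.30, high = 0.46),
    dist_spec("discount_rate", 0.05, "fixed", low = 0, high = 0.08),
    dist_spec("drug_price_per_mg", 37.2, "gamma", sd = 3.72, low = 36.24, high = 48.84),
    dist_spec("weight_kg", 75, "beta", sd = 12.5, low = 50, high = 120,
              scale_low = 50, scale_high = 120),
    dist_spec("infusion_first_hour", 15.6, "gamma", sd = 1.56, low = 5, high = 30),
    dist_spec("infusion_additional_hour", 1, "gamma", sd = 0.1, low = 0.5, high = 2),
    dist_spec("acute_mrs0_1", 12336, "gamma", sd = 2102, low = 7126, high = 15533),
    dist_spec("acute_mrs2_5", 16311, "gamma", sd = 3106, low = 8964, high = 21389),
    dist_spec("acute_death", 13979, "gamma", sd = 2977, low = 6568, high = 18476),
    dist_spec("cost_sich", 2979, "gamma", sd = 1393, low = 647, high = 6217),
    dist_spec("posthosp_mrs0_1", 8771, "gamma", sd = 2140, low = 2626, high = 11188),
    dist_spec("posthosp_mrs2_5", 13345, "gamma", sd = 3356, low = 3356, high = 16783),
    dist_spec("cost_recurrent", 18180, "gamma", sd = 2272, low = 13635, high = 22726)
  )
  names(params) <- vapply(params, function(p) p$name, character(1))
  scenario_config(
    country = "china", currency = "CNY", start_age = 68, horizon_years = 20,
    cycle_length_years = 0.25, wtp = 85698,
    mrs_month3 = list(
      tirofiban = mrs_distribution(c(0.106, 0.185, 0.329, 0.219, 0.106, 0.017, 0.038)),
      aspirin = mrs_distribution(c(0.083, 0.139, 0.342, 0.291, 0.102, 0.016, 0.027))),
    params = params,
    acute_map = list(acute_mrs0_1 = 1:2, acute_mrs2_5 = 3:6, acute_death = 7),
    posthosp = list(period = "annual",
                    map = list(posthosp_mrs0_1 = 1:2, posthosp_mrs2_5 = 3:6)),
    life_table = china_life_table())
}

#' Built-in US scenario
#'
#' The published US parameter set: USD costs, 3% discount rate, WTP $100,000
#' per QALY, 90 kg patients, per-state quarterly post-hospitalisation costs.
#' Background mortality uses the shipped synthetic placeholder life table
#' ([us_placeholder_life_table()]); the source's own US table is not public, so
#' US absolute levels carry a wider tolerance than China's.
#'
#' @return A `scenario_config`.
#' @export
us_base <- function() {
  params <- list(
    dist_spec("p_sich_tirofiban", 0.01, "beta", sd = 0.003, low = 0, high = 0.01),
    dist_spec("p_sich_aspirin", 0, "fixed"),
    dist_spec("p_recurrent_annual", 0.013, "beta", sd = 0.001, low = 0.010, high = 0.015),
    dist_spec("p_death_after_recurrence", 0.19, "beta", sd = 0.051, low = 0.1, high = 0.3),
    dist_spec("hr_mrs0", 1, "lognormal", sd = 0.050, low = 1, high = 1.2, truncate_low = 1),
    dist_spec("hr_mrs1", 1, "lognormal", sd = 0.050, low = 1, high = 1.2, truncate_low = 1),
    dist_spec("hr_mrs2", 1.11, "lognormal", sd = 0.103, low = 1, high = 1.3, truncate_low = 1),
    dist_spec("hr_mrs3", 1.27, "lognormal", sd = 0.125, low = 1.02, high = 1.52, truncate_low = 1),
    dist_spec("hr_mrs4", 1.71, "lognormal", sd = 0.170, low = 1.37, high = 2.05, truncate_low = 1),
    dist_spec("hr_mrs5", 2.37, "lognormal", sd = 0.235, low = 1.9, high = 2.84, truncate_low = 1),
    dist_spec("u_mrs0", 0.85, "beta", sd = 0.051, low = 0.8, high = 1),
    dist_spec("u_mrs1", 0.80, "beta", sd = 0.038, low = 0.8, high = 0.95),
    dist_spec("u_mrs2", 0.70, "beta", sd = 0.055, low = 0.68, high = 0.9),
    dist_spec("u_mrs3", 0.51, "beta", sd = 0.050, low = 0.45, high = 0.65),
    dist_spec("u_mrs4", 0.30, "beta", sd = 0.075, low = 0.1, high = 0.4),
    dist_spec("u_mrs5", 0.15, "beta", sd = 0.080, low = 0, high = 0.32),
    dist_spec("u_recurrence", 0.31, "beta", sd = 0.033, low = 0.24, high = 0.37),
    dist_spec("du_sich", 0.38, "beta", sd = 0.040, low = 0.3, high = 0.46),
    dist_spec("discount_rate", 0.03, "fixed", low = 0, high = 0.08),
    dist_spec("drug_price_per_mg", 19.29, "gamma", sd = 1.93, low = 9.64, high = 38.57),
    dist_spec("weight_kg", 90, "beta", sd = 15, low = 60, high = 150,
              scale_low = 60, scale_high = 150),
    dist_spec("infusion_first_hour", 142.55, "gamma", sd = 14.3, low = 100, high = 200),
    dist_spec("infusion_additional_hour", 30.68, "gamma", sd = 3.07, low = 20, high = 40),
    dist_spec("acute_mrs0_2", 15561, "gamma", sd = 1556, low = 15375, high = 15748),
    dist_spec("acute_mrs3_5", 19345, "gamma", sd = 1935, low = 19108, high = 19581),
    dist_spec("acute_death", 25425, "gamma", sd = 2543, low = 24469, high = 26382),
    dist_spec("cost_sich", 3678, "gamma", sd = 368, low = 2942, high = 4414),
    dist_spec("posthosp_mrs0", 3069, "gamma", sd = 307, low = 2455, high = 3682),
    dist_spec("posthosp_mrs1", 2966, "gamma", sd = 297, low = 2528, high = 3791),
    dist_spec("posthosp_mrs2", 3655, "gamma", sd = 366, low = 2925, high = 4386),
    dist_spec("posthosp_mrs3", 6277, "gamma", sd = 628, low = 5022, high = 7532),
    dist_spec("posthosp_mrs4", 12705, "gamma", sd = 1271, low = 10163, high = 15246),
    dist_spec("posthosp_mrs5", 18678, "gamma", sd = 1868, low = 14942, high = 22413),
    dist_spec("cost_recurrent", 22274, "gamma", sd = 2227, low = 21590, high = 23034)
  )
  names(params) <- vapply(params, function(p) p$name, character(1))
  scenario_config(
    country = "us", currency = "USD", start_age = 68, horizon_years = 20,
    cycle_length_years = 0.25, wtp = 100000,
    mrs_month3 = list(
      tirofiban = mrs_distribution(c(0.106, 0.185, 0.329, 0.219, 0.106, 0.017, 0.038)),
      aspirin = mrs_distribution(c(0.083, 0.139, 0.342, 0.291, 0.102, 0.016, 0.027))),
    params = params,
    acute_map = list(acute_mrs0_2 = 1:3, acute_mrs3_5 = 4:6, acute_death = 7),
    posthosp = list(period = "quarterly",
                    map = as.list(stats::setNames(1:6, paste0("posthosp_mrs", 0:5)))),
    life_table = us_placeholder_life_table())
}

#' Load a scenario by name or from a config file
#'
#' @param source `"china_base"`, `"us_base"`, or a path to a YAML/JSON scenario
#'   file written by [save_scenario()].
#' @return A validated `scenario_config`.
#' @export
load_scenario <- function(source) {
  if (source %in% c("china_base", "us_base")) {
    return(switch(source, china_base = china_base(), us_base = us_base()))
  }
  if (!file.exists(source)) {
    stop(sprintf("unknown scenario '%s'; built-ins are 'china_base' and 'us_base'", source),
         call. = FALSE)
  }
  raw <- if (grepl("\\.json$", source, ignore.case = TRUE)) {
    jsonlite::read_json(source, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(source)
  }
  scenario_from_list(raw)
}

#' Serialise a scenario to YAML or JSON
#'
#' @param cfg A `scenario_config`.
#' @param path Destination; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
save_scenario <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario_config"))
  lst <- scenario_to_list(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(lst, path, precision = 15)
  }
  invisible(path)
}

scenario_to_list <- function(cfg) {
  specs <- lapply(cfg$params, function(p) {
    out <- list(base = p$base, family = p$family)
    if (is.finite(p$sd)) out$sd <- p$sd
    if (is.finite(p$low)) { out$low <- p$low; out$high <- p$high }
    if (!is.null(p$scale_low)) { out$scale_low <- p$scale_low; out$scale_high <- p$scale_high }
    if (!is.null(p$truncate_low)) out$truncate_low <- p$truncate_low
    out
  })
  list(country = cfg$country, currency = cfg$currency, start_age = cfg$start_age,
       horizon_years = cfg$horizon_years, cycle_length_years = cfg$cycle_length_years,
       wtp = cfg$wtp,
       mrs_month3 = lapply(cfg$mrs_month3, function(m) as.numeric(m)),
       state_names = cfg$state_names, hr_params = cfg$hr_params,
       utility_params = cfg$utility_params,
       acute_map = cfg$acute_map,
       posthosp = cfg$posthosp,
       life_table = list(age_start = cfg$life_table$age_start,
                         age_end = cfg$life_table$age_end,
                         annual_death_prob = cfg$life_table$annual_death_prob),
       psa_ess = cfg$psa_ess, regimen = cfg$regimen,
       sich_exposure_years = cfg$sich_exposure_years,
       toggles = cfg$toggles, params = specs)
}

scenario_from_list <- function(lst) {
  need <- c("country", "currency", "start_age", "horizon_years", "cycle_length_years",
            "wtp", "mrs_month3", "params", "life_table", "acute_map", "posthosp")
  missing <- setdiff(need, names(lst))
  if (length(missing)) {
    stop("scenario file: missing fields: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  params <- lapply(names(lst$params), function(nm) {
    p <- lst$params[[nm]]
    dist_spec(nm, p$base, p$family,
              sd = if (is.null(p$sd)) NA_real_ else p$sd,
              low = if (is.null(p$low)) NA_real_ else p$low,
              high = if (is.null(p$high)) NA_real_ else p$high,
              scale_low = p$scale_low, scale_high = p$scale_high,
              truncate_low = p$truncate_low)
  })
  names(params) <- names(lst$params)
  S <- length(lst$state_names)
  mk_mrs <- if (S == 7) mrs_distribution else function(x) as.numeric(x)
  scenario_config(
    country = lst$country, currency = lst$currency, start_age = lst$start_age,
    horizon_years = lst$horizon_years, cycle_length_years = lst$cycle_length_years,
    wtp = lst$wtp,
    mrs_month3 = lapply(lst$mrs_month3, mk_mrs),
    params = params, state_names = lst$state_names,
    hr_params = lst$hr_params, utility_params = lst$utility_params,
    acute_map = lapply(lst$acute_map, as.integer),
    posthosp = list(period = lst$posthosp$period,
                    map = lapply(lst$posthosp$map, as.integer)),
    life_table = life_table(lst$life_table$age_start, lst$life_table$age_end,
                            lst$life_table$annual_death_prob),
    psa_ess = lst$psa_ess, regimen = lst$regimen,
    sich_exposure_years = lst$sich_exposure_years,
    toggles = lst$toggles)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config '%s' (%s)>\n", x$country, x$currency))
  cat(sprintf("  start age %g, horizon %g y, cycle %g y, discount %g, WTP %s %s/QALY\n",
              x$start_age, x$horizon_years, x$cycle_length_years,
              x$params$discount_rate$base, format(x$wtp, big.mark = ","), x$currency))
  cat(sprintf("  %d states, %d parameters, life table %d bands\n",
              length(x$state_names), length(x$params), nrow(x$life_table)))
  invisible(x)
}
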