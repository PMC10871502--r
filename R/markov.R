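#' Convert an annual probability to a 3-month cycle probability
#'
#' The standard rate-based conversion: the annual probability `R` becomes a
#' quarterly rate `r = -ln(1 - R) / 4`, and the cycle probability is
#' `p = 1 - exp(-r)`, i.e. `1 - (1 - R)^(1/4)`.
#'
#' @param R Annual probability in `[0, 1)`.
#' @param cycles_per_year Number of cycles per year (4 for 3-month cycles).
#' @return Cycle probability.
#' @export
annual_rate_to_cycle_prob <- function(R, cycles_per_year = 4) {
  if (any(!is.finite(R)) || any(R < 0) || any(R >= 1)) {
    stop("annual_rate_to_cycle_prob: R must lie in [0, 1)", call. = FALSE)
  }
  1 - exp(log(1 - R) / cycles_per_year)
}

#' Hazard-ratio-adjusted background death probability per cycle
#'
#' Converts an annual background death probability to a rate, scales it by a
#' disability-level hazard ratio, and converts back to a cycle probability:
#' `p = 1 - exp(-hr * (-ln(1 - annual_prob)) / 4)`.
#'
#' This is the textbook conversion. Note the engine's default
#' `mortality_conversion = "annual_per_cycle"` toggle instead applies the
#' HR-scaled *annual* probability each cycle (see the methods vignette for why
#' that reproduction-mode convention exists).
#'
#' @param annual_prob Annual death probability in `[0, 1)`.
#' @param hr Hazard ratio, `>= 1`.
#' @param cycles_per_year Number of cycles per year.
#' @return Cycle death probability.
#' @export
adjusted_background_death_prob <- function(annual_prob, hr, cycles_per_year = 4) {
  if (any(!is.finite(annual_prob)) || any(annual_prob < 0) || any(annual_prob >= 1)) {
    stop("adjusted_background_death_prob: annual_prob must lie in [0, 1)", call. = FALSE)
  }
  if (any(!is.finite(hr)) || any(hr < 0)) {
    stop("adjusted_background_death_prob: hr must be nonnegative", call. = FALSE)
  }
  1 - exp(-hr * (-log(1 - annual_prob)) / cycles_per_year)
}

#' Discount factor at a given cycle
#'
#' `(1 + annual_rate)^-(cycle_index * cycle_length_years)`.
#'
#' @param annual_rate Annual discount rate, `>= 0`.
#' @param cycle_index Cycle number (0 = the acute quarter, undiscounted).
#' @param cycle_length_years Cycle length in years.
#' @return Discount factor in `(0, 1]`.
#' @export
discount_factor <- function(annual_rate, cycle_index, cycle_length_years = 0.25) {
  if (any(annual_rate < 0)) stop("discount_factor: rate must be nonnegative", call. = FALSE)
  (1 + annual_rate)^(-(cycle_index * cycle_length_years))
}

#' Build the one-cycle transition matrix
#'
#' For each living state `i`: with cycle recurrence probability `q` a recurrent
#' stroke occurs, of which a fraction `d` dies; survivors redistribute evenly
#' over the states with comparable or higher disability (`i..worst`, or
#' `i+1..worst` when `include_source = FALSE`). With probability `1 - q`,
#' background death occurs at the state's HR-adjusted cycle probability `b[i]`,
#' otherwise the patient remains in state `i`. Death is absorbing. Patients
#' never transition to a lower disability level.
#'
#' @param q Cycle probability of recurrent stroke.
#' @param d Probability of death given recurrence.
#' @param b Vector of cycle background death probabilities, one per living
#'   state (already HR-adjusted).
#' @param include_source Do recurrence survivors include their own state in the
#'   redistribution? (Default TRUE; from the worst living state survivors stay
#'   put either way.)
#' @return Row-stochastic matrix, states x states, death last.
#' @export
build_transition_matrix <- function(q, d, b, include_source = TRUE) {
  stopifnot(q >= 0, q <= 1, d >= 0, d <= 1, all(b >= 0), all(b <= 1))
  A <- length(b)
  S <- A + 1
  M <- matrix(0, S, S)
  for (i in seq_len(A)) {
    targets <- if (include_source) i:A else if (i < A) (i + 1):A else A
    M[i, targets] <- M[i, targets] + q * (1 - d) / length(targets)
    M[i, S] <- q * d + (1 - q) * b[i]
    M[i, i] <- M[i, i] + (1 - q) * (1 - b[i])
  }
  M[S, S] <- 1
  M
}

# Precompute everything a cohort run needs that does not depend on the arm:
# per-cycle background-death matrix, discount factors, utilities, costs.
engine_prep <- function(cfg, values) {
  S <- length(cfg$state_names)
  A <- S - 1
  cl <- cfg$cycle_length_years
  n_cycles <- round(cfg$horizon_years / cl) - 1

  q <- annual_rate_to_cycle_prob(values[["p_recurrent_annual"]], 1 / cl)
  d <- values[["p_death_after_recurrence"]]
  hr <- as.numeric(values[cfg$hr_params])
  u <- as.numeric(values[cfg$utility_params])

  ages <- cfg$start_age + cl * seq_len(n_cycles)
  pa <- life_table_lookup(cfg$life_table, ages)
  r_annual <- -log(1 - pa)
  # b: n_cycles x A matrix of per-cycle background death probabilities
  b <- switch(cfg$toggles$mortality_conversion,
    annual_per_cycle = 1 - exp(-outer(r_annual, hr)),
    quarterly = 1 - exp(-outer(r_annual, hr) * cl),
    stop("unknown mortality_conversion toggle", call. = FALSE))

  dr <- values[["discount_rate"]]
  disc <- discount_factor(dr, seq_len(n_cycles), cl)
  disc_cost <- if (isTRUE(cfg$toggles$discount_costs)) disc else rep(1, n_cycles)
  disc_eff <- if (isTRUE(cfg$toggles$discount_effects)) disc else rep(1, n_cycles)

  # quarterly post-hospitalisation cost per living state; death accrues nothing
  qc <- numeric(A)
  for (nm in names(cfg$posthosp$map)) qc[cfg$posthosp$map[[nm]]] <- values[[nm]]
  if (cfg$posthosp$period == "annual") qc <- qc * cl

  u_rec <- switch(cfg$toggles$recurrence_utility_mode,
    absolute = rep(values[["u_recurrence"]], A),
    decrement = pmax(u - values[["u_recurrence"]], 0),
    stop("unknown recurrence_utility_mode toggle", call. = FALSE))

  list(S = S, A = A, cl = cl, n_cycles = n_cycles, q = q, d = d, b = b,
       u = u, u_rec = u_rec, qc = qc,
       cost_recurrent = values[["cost_recurrent"]],
       disc_cost = disc_cost, disc_eff = disc_eff, ages = ages,
       include_source = isTRUE(cfg$toggles$recurrence_includes_source),
       half_cycle = isTRUE(cfg$toggles$half_cycle))
}

# Evolve one cohort. Returns totals, and the full trace when keep_trace = TRUE.
engine_run <- function(initial, prep, keep_trace = FALSE) {
  A <- prep$A; S <- prep$S
  q <- prep$q; d <- prep$d
  occ <- as.numeric(initial)
  tc <- 0; tq <- 0
  if (keep_trace) {
    occ_m <- matrix(0, prep$n_cycles + 1, S)
    occ_m[1, ] <- occ
    cyc_cost <- numeric(prep$n_cycles + 1)
    cyc_qaly <- numeric(prep$n_cycles + 1)
    rec_ev <- numeric(prep$n_cycles + 1)
  }
  for (k in seq_len(prep$n_cycles)) {
    alive <- occ[seq_len(A)]
    rec <- q * alive
    rec_s <- (1 - d) * rec
    nonrec <- (1 - q) * alive
    bk <- prep$b[k, ]
    stay <- nonrec * (1 - bk)
    newa <- stay
    for (j in seq_len(A)) {
      if (rec_s[j] == 0) next
      targets <- if (prep$include_source) j:A else if (j < A) (j + 1):A else A
      newa[targets] <- newa[targets] + rec_s[j] / length(targets)
    }
    dead <- occ[S] + d * sum(rec) + sum(nonrec * bk)
    prev_alive <- alive
    occ <- c(newa, dead)

    rec_total <- sum(rec)
    if (prep$half_cycle) {
      state_cost <- sum((prev_alive + newa) / 2 * prep$qc)
      state_qaly <- (sum(prev_alive * prep$u) +
                     sum(stay * prep$u) + sum(rec_s * prep$u_rec)) / 2
    } else {
      state_cost <- sum(newa * prep$qc)
      state_qaly <- sum(stay * prep$u) + sum(rec_s * prep$u_rec)
    }
    ck <- prep$disc_cost[k] * (state_cost + rec_total * prep$cost_recurrent)
    qk <- prep$disc_eff[k] * prep$cl * state_qaly
    tc <- tc + ck
    tq <- tq + qk
    if (keep_trace) {
      occ_m[k + 1, ] <- occ
      cyc_cost[k + 1] <- ck
      cyc_qaly[k + 1] <- qk
      rec_ev[k + 1] <- rec_total
    }
  }
  out <- list(cost = tc, qaly = tq)
  if (keep_trace) {
    out$trace <- data.frame(cycle = 0:prep$n_cycles,
                            age = c(prep$ages[1] - prep$cl, prep$ages),
                            occ_m, cost = cyc_cost, qaly = cyc_qaly,
                            recurrence_events = rec_ev)
  }
  out
}

#' Evolve a cohort through the Markov stage
#'
#' Starting from the month-3 distribution (cycle 0, no accrual: the decision
#' tree owns the acute quarter), runs `horizon / cycle_length - 1` cycles of
#' recurrent stroke, even redistribution of recurrence survivors to
#' equal-or-worse states, HR-adjusted background mortality, and discounted
#' cost/QALY accrual. Per-cycle state costs use the post-hospitalisation
#' schedule (annual costs spread over the year's cycles; death accrues
#' nothing); each recurrence event is charged the recurrent-stroke cost once;
#' recurrence survivors accrue the recurrence utility instead of their state
#' utility during that cycle.
#'
#' @param initial Probability vector over the health states at month 3.
#' @param cfg A `scenario_config`.
#' @param values Parameter values (default the base case).
#' @return A `cohort_trace` data frame: cycle, age, one occupancy column per
#'   state, discounted per-cycle `cost` and `qaly`, and recurrence events.
#'   Totals are in `attr(, "totals")`.
#' @export
run_cohort <- function(initial, cfg, values = base_values(cfg)) {
  initial <- as.numeric(initial)
  S <- length(cfg$state_names)
  if (length(initial) != S) stop("run_cohort: initial has wrong length", call. = FALSE)
  if (any(initial < 0) || abs(sum(initial) - 1) > 1e-9) {
    stop("run_cohort: initial must be a probability distribution", call. = FALSE)
  }
  prep <- engine_prep(cfg, values)
  res <- engine_run(initial, prep, keep_trace = TRUE)
  trace <- res$trace
  names(trace)[3:(2 + S)] <- cfg$state_names
  attr(trace, "totals") <- c(cost = res$cost, qaly = res$qaly)
  class(trace) <- c("cohort_trace", "data.frame")
  trace
}

#' Write a cohort trace to CSV
#'
#' @param trace A `cohort_trace`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
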