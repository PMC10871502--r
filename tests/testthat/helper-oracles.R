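# Independent oracles for the Markov engine. Both re-derive the event model
# from scratch (probabilities, accrual rules, discounting) without touching the
# engine internals, so agreement certifies the cohort arithmetic.

# Shared re-derivation of the per-cycle inputs an oracle needs.
oracle_inputs <- function(cfg, values) {
  S <- length(cfg$state_names); A <- S - 1
  cl <- cfg$cycle_length_years
  n_cycles <- round(cfg$horizon_years / cl) - 1
  q <- 1 - (1 - values[["p_recurrent_annual"]])^cl
  d <- values[["p_death_after_recurrence"]]
  hr <- as.numeric(values[cfg$hr_params])
  u <- as.numeric(values[cfg$utility_params])
  u_rec <- if (cfg$toggles$recurrence_utility_mode == "absolute") {
    rep(values[["u_recurrence"]], A)
  } else {
    pmax(u - values[["u_recurrence"]], 0)
  }
  qc <- numeric(A)
  for (nm in names(cfg$posthosp$map)) qc[cfg$posthosp$map[[nm]]] <- values[[nm]]
  if (cfg$posthosp$period == "annual") qc <- qc * cl
  ages <- cfg$start_age + cl * seq_len(n_cycles)
  lt <- cfg$life_table
  pa <- lt$annual_death_prob[pmin(findInterval(ages, lt$age_start), nrow(lt))]
  b <- if (cfg$toggles$mortality_conversion == "annual_per_cycle") {
    1 - outer(1 - pa, hr, `^`)
  } else {
    1 - outer(1 - pa, hr * cl, `^`)
  }
  dr <- values[["discount_rate"]]
  disc <- (1 + dr)^(-cl * seq_len(n_cycles))
  list(S = S, A = A, cl = cl, n_cycles = n_cycles, q = q, d = d, u = u,
       u_rec = u_rec, qc = qc, cost_rec = values[["cost_recurrent"]], b = b,
       disc_c = if (isTRUE(cfg$toggles$discount_costs)) disc else rep(1, n_cycles),
       disc_e = if (isTRUE(cfg$toggles$discount_effects)) disc else rep(1, n_cycles),
       include_source = isTRUE(cfg$toggles$recurrence_includes_source))
}

# Exhaustive enumeration over every event path of a collapsed scenario.
# Events per cycle from living state i: recurrence-death, recurrence-survival
# to each admissible destination, background death, stay. Accruals follow the
# model's accounting: each recurrence event is charged the recurrent-stroke
# cost; end-of-cycle living states accrue the state cost; stayers accrue their
# state utility and recurrence survivors the recurrence utility.
path_enum_totals <- function(cfg, initial, values = base_values(cfg)) {
  inp <- oracle_inputs(cfg, values)
  total <- c(cost = 0, qaly = 0)
  recurse <- function(k, state, prob, cost, qaly) {
    if (prob == 0) return()
    if (k > inp$n_cycles || state == inp$S) {
      total <<- total + prob * c(cost, qaly)
      return()
    }
    i <- state
    dc <- inp$disc_c[k]; de <- inp$disc_e[k]
    # recurrence, fatal
    recurse(k + 1, inp$S, prob * inp$q * inp$d, cost + dc * inp$cost_rec, qaly)
    # recurrence, survived: even spread over admissible destinations
    targets <- if (inp$include_source) i:inp$A else if (i < inp$A) (i + 1):inp$A else inp$A
    pt <- inp$q * (1 - inp$d) / length(targets)
    for (t in targets) {
      recurse(k + 1, t, prob * pt,
              cost + dc * (inp$cost_rec + inp$qc[t]),
              qaly + de * inp$cl * inp$u_rec[i])
    }
    bk <- inp$b[k, i]
    # no recurrence, background death
    recurse(k + 1, inp$S, prob * (1 - inp$q) * bk, cost, qaly)
    # no recurrence, stay
    recurse(k + 1, i, prob * (1 - inp$q) * (1 - bk),
            cost + dc * inp$qc[i], qaly + de * inp$cl * inp$u[i])
  }
  for (s in seq_len(inp$S)) recurse(1, s, initial[s], 0, 0)
  total
}

# Individual-level microsimulation of the Markov stage (vectorised over
# patients). Returns mean per-patient cost/QALY and their Monte-Carlo SEs.
microsim_totals <- function(cfg, initial, values = base_values(cfg),
                            n_patients = 60000, seed = 42) {
  inp <- oracle_inputs(cfg, values)
  set.seed(seed)
  state <- sample.int(inp$S, n_patients, replace = TRUE, prob = initial)
  cost <- qaly <- numeric(n_patients)
  for (k in seq_len(inp$n_cycles)) {
    alive <- state < inp$S
    if (!any(alive)) break
    rec <- alive & (stats::runif(n_patients) < inp$q)
    cost[rec] <- cost[rec] + inp$disc_c[k] * inp$cost_rec
    rec_die <- rec & (stats::runif(n_patients) < inp$d)
    rec_srv <- rec & !rec_die
    if (any(rec_srv)) {
      i <- state[rec_srv]
      if (inp$include_source) {
        dest <- i + floor(stats::runif(sum(rec_srv)) * (inp$A - i + 1))
      } else {
        dest <- ifelse(i < inp$A,
                       i + 1 + floor(stats::runif(sum(rec_srv)) * (inp$A - i)),
                       inp$A)
      }
      qaly[rec_srv] <- qaly[rec_srv] + inp$disc_e[k] * inp$cl * inp$u_rec[i]
      state[rec_srv] <- dest
    }
    nonrec <- alive & !rec
    bg_die <- nonrec & (stats::runif(n_patients) < inp$b[cbind(k, pmin(state, inp$A))])
    stayed <- nonrec & !bg_die
    qaly[stayed] <- qaly[stayed] + inp$disc_e[k] * inp$cl * inp$u[state[stayed]]
    state[rec_die | bg_die] <- inp$S
    alive_end <- state < inp$S
    cost[alive_end] <- cost[alive_end] + inp$disc_c[k] * inp$qc[state[alive_end]]
  }
  list(cost = mean(cost), qaly = mean(qaly),
       se_cost = stats::sd(cost) / sqrt(n_patients),
       se_qaly = stats::sd(qaly) / sqrt(n_patients))
}

# Every combination of the binary/categorical engine toggles.
toggle_grid <- function() {
  expand.grid(half_cycle = c(FALSE, TRUE),
              recurrence_includes_source = c(TRUE, FALSE),
              infusion_in_aspirin = c(FALSE, TRUE),
              recurrence_utility_mode = c("absolute", "decrement"),
              mortality_conversion = c("annual_per_cycle", "quarterly"),
              discount_costs = c(FALSE, TRUE),
              stringsAsFactors = FALSE)
}

with_toggles <- function(cfg, row) {
  for (nm in names(row)) cfg$toggles[[nm]] <- row[[nm]]
  cfg
}
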