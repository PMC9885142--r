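# The four-state annual-cycle Markov cohort engine.
#
# States: SAFE_FIX (successful fixation, lag screw inside the TAD < 20 mm
# safe zone), UNSAFE_FIX (successful fixation outside the safe zone),
# SALVAGE_THA (salvage total hip arthroplasty after fixation failure),
# DEAD (absorbing).
#
# Event order within a cycle: (a) background death - the first-year excess
# mortality in cycle 1 for fixation states, the age-specific life-table
# rate otherwise and for the salvage state; (b) surviving fixation
# occupants fail at the zone-specific annual rate; failures undergo
# salvage THA with its own perioperative mortality, survivors enter
# SALVAGE_THA; (c) utility accrues on end-of-cycle occupancy, plus the
# convention-controlled fraction for in-cycle decedents; the one-time
# salvage disutility applies to patients entering the salvage state.

.state_names <- c("safe", "unsafe", "salvage", "dead")

#' Initial state distribution after surgery
#'
#' Perioperative deaths go straight to DEAD; survivors split between safe
#' and unsafe fixation according to the strategy's safe-zone probability.
#'
#' @param strategy `"navigated"` or `"traditional"`.
#' @param params An [imn_parameters()] object.
#' @return Named numeric state vector (`safe`, `unsafe`, `salvage`,
#'   `dead`) summing to 1.
#' @examples
#' initial_distribution("navigated", default_parameters())
#' @export
initial_distribution <- function(strategy = c("navigated", "traditional"),
                                 params = default_parameters()) {
  strategy <- match.arg(strategy)
  cl <- params$clinical
  p_safe <- if (strategy == "navigated") cl$p_safe_nav else cl$p_safe_trad
  m <- cl$p_periop_death_imn
  setNames(c((1 - m) * p_safe, (1 - m) * (1 - p_safe), 0, m), .state_names)
}

# death probability of fixation states in a given cycle
.fix_death_prob <- function(cycle, qx, params, conventions) {
  if (cycle == 1L) {
    m1 <- params$clinical$p_death_first_year
    mp <- params$clinical$p_periop_death_imn
    if (conventions$first_year_mortality_includes_periop)
      max(0, (m1 - mp) / (1 - mp))
    else m1
  } else qx
}

#' Advance the cohort one cycle
#'
#' Applies one annual cycle of the event sequence (background death, then
#' fixation failure with salvage THA, then utility/cost accrual) to a
#' state vector.  Returned cost and QALY amounts are undiscounted;
#' [run_cohort()] applies discounting.
#'
#' @param state Named state vector as from [initial_distribution()].
#' @param cycle_index Cycle number, 1-based.
#' @param strategy `"navigated"` or `"traditional"` (selects the annual
#'   utility of the fixation states).
#' @param params An [imn_parameters()] object.
#' @param conventions A [model_conventions()] object.
#' @return List with `state` (end-of-cycle vector), `cycle_cost`,
#'   `cycle_qaly`, `new_salvage` (fraction of the cohort entering the
#'   salvage state this cycle) and `salvage_operations` (fraction
#'   undergoing the salvage procedure, including its perioperative
#'   deaths).
#' @export
cycle_transition <- function(state, cycle_index, strategy, params,
                             conventions = model_conventions()) {
  stopifnot(cycle_index >= 1)
  cl <- params$clinical; ut <- params$utilities
  u_fix <- if (strategy == "navigated") ut$u_nav else ut$u_trad
  age <- params$economics$start_age + cycle_index - 1L
  qx <- lookup_qx(params$life_table, age)
  pd_fix <- .fix_death_prob(cycle_index, qx, params, conventions)

  start <- state
  d_safe <- state[["safe"]] * pd_fix
  d_unsafe <- state[["unsafe"]] * pd_fix
  d_salv <- state[["salvage"]] * qx
  s_safe <- state[["safe"]] - d_safe
  s_unsafe <- state[["unsafe"]] - d_unsafe
  s_salv <- state[["salvage"]] - d_salv

  fail <- s_safe * cl$annual_fail_safe + s_unsafe * cl$annual_fail_unsafe
  entrants <- fail * (1 - cl$p_periop_death_tha)
  s_safe <- s_safe * (1 - cl$annual_fail_safe)
  s_unsafe <- s_unsafe * (1 - cl$annual_fail_unsafe)

  new_state <- setNames(c(
    s_safe, s_unsafe, s_salv + entrants,
    state[["dead"]] + d_safe + d_unsafe + d_salv +
      fail * cl$p_periop_death_tha), .state_names)

  cycle_cost <- fail * params$costs$cost_tha

  if (conventions$half_cycle_correction) {
    qaly <- (start[["safe"]] + start[["unsafe"]] + s_safe + s_unsafe) / 2 * u_fix +
      (start[["salvage"]] + new_state[["salvage"]]) / 2 * ut$u_tha
  } else {
    f <- conventions$dying_cycle_utility_fraction
    qaly <- (s_safe + s_unsafe) * u_fix + new_state[["salvage"]] * ut$u_tha +
      f * ((d_safe + d_unsafe + fail * cl$p_periop_death_tha) * u_fix +
             d_salv * ut$u_tha)
  }
  qaly <- qaly + ut$disutility_salvage * entrants

  list(state = new_state, cycle_cost = cycle_cost, cycle_qaly = qaly,
       new_salvage = entrants, salvage_operations = fail)
}

#' Run the Markov cohort for one strategy
#'
#' Evaluates a strategy over the model horizon: the initial distribution,
#' `horizon` cycle transitions, discounting at the annual rate, cycle-zero
#' surgery costs (IMN for every patient entering surgery, plus the
#' per-patient navigation cost for the navigated arm) and, per convention,
#' the initial utility accrual.
#'
#' The reported `salvage_rate` is the undiscounted cumulative incidence of
#' entry into the salvage state (the fraction of the cohort that lives in
#' the SALVAGE_THA state at some point); the cumulative fraction undergoing
#' the salvage operation, which also counts its perioperative deaths, is
#' reported as `salvage_operations`.
#'
#' @inheritParams cycle_transition
#' @param strategy `"navigated"` or `"traditional"`.
#' @param include_navigation_cost Charge the per-patient navigation cost
#'   in the navigated arm (disable to inspect the clinical cost base).
#' @param trace Keep the per-cycle trace (a data frame)?
#' @return A `strategy_outcome`: list with `strategy`, `total_cost`,
#'   `total_qaly` (both discounted), `salvage_rate`,
#'   `salvage_operations`, `final_salvage_occupancy` and, if requested,
#'   `trace`.
#' @examples
#' run_cohort("traditional", default_parameters())
#' @export
run_cohort <- function(strategy = c("navigated", "traditional"),
                       params = default_parameters(),
                       conventions = model_conventions(),
                       include_navigation_cost = TRUE,
                       trace = TRUE) {
  strategy <- match.arg(strategy)
  ec <- params$economics; ut <- params$utilities
  r <- ec$discount_rate
  horizon <- as.integer(ec$horizon)
  u_fix <- if (strategy == "navigated") ut$u_nav else ut$u_trad

  state <- initial_distribution(strategy, params)
  df0 <- if (conventions$discount_cycle_zero) 1 / (1 + r) else 1

  cost0 <- params$costs$cost_imn
  if (strategy == "navigated" && include_navigation_cost)
    cost0 <- cost0 + nav_cost_per_patient(params$costs)
  qaly0 <- if (conventions$initial_utility_accrual)
    (state[["safe"]] + state[["unsafe"]]) * u_fix else 0

  total_cost <- cost0 * df0
  total_qaly <- qaly0 * df0
  cum_salvage <- 0
  cum_ops <- 0

  if (trace) {
    tr <- data.frame(cycle = 0:horizon, age = ec$start_age + 0:horizon,
                     safe = NA_real_, unsafe = NA_real_, salvage = NA_real_,
                     dead = NA_real_, cycle_cost = NA_real_, cycle_qaly = NA_real_,
                     disc_cost = NA_real_, disc_qaly = NA_real_,
                     new_salvage = NA_real_, cum_salvage = NA_real_)
    tr[1, .state_names] <- state
    tr$cycle_cost[1] <- cost0; tr$cycle_qaly[1] <- qaly0
    tr$disc_cost[1] <- cost0 * df0; tr$disc_qaly[1] <- qaly0 * df0
    tr$new_salvage[1] <- 0; tr$cum_salvage[1] <- 0
  }

  for (t in seq_len(horizon)) {
    step <- cycle_transition(state, t, strategy, params, conventions)
    state <- step$state
    df <- (1 + r)^(-t)
    total_cost <- total_cost + step$cycle_cost * df
    total_qaly <- total_qaly + step$cycle_qaly * df
    cum_salvage <- cum_salvage + step$new_salvage
    cum_ops <- cum_ops + step$salvage_operations
    if (trace) {
      tr[t + 1, .state_names] <- state
      tr$cycle_cost[t + 1] <- step$cycle_cost
      tr$cycle_qaly[t + 1] <- step$cycle_qaly
      tr$disc_cost[t + 1] <- step$cycle_cost * df
      tr$disc_qaly[t + 1] <- step$cycle_qaly * df
      tr$new_salvage[t + 1] <- step$new_salvage
      tr$cum_salvage[t + 1] <- cum_salvage
    }
  }

  structure(list(strategy = strategy, total_cost = total_cost,
                 total_qaly = total_qaly, salvage_rate = cum_salvage,
                 salvage_operations = cum_ops,
                 final_salvage_occupancy = state[["salvage"]],
                 trace = if (trace) tr else NULL),
            class = "strategy_outcome")
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("%s IMN: %.2f QALYs, cost %s, salvage incidence %.1f%%\n",
              x$strategy, x$total_qaly,
              format(round(x$total_cost), big.mark = ","),
              100 * x$salvage_rate))
  invisible(x)
}

#' Export a cohort trace to CSV
#'
#' @param outcome A `strategy_outcome` produced with `trace = TRUE`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(outcome, path) {
  stopifnot(inherits(outcome, "strategy_outcome"), !is.null(outcome$trace))
  write.csv(outcome$trace, path, row.names = FALSE)
  invisible(path)
}
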