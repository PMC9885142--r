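# Patient-level microsimulation oracle.  Simulates individual patients
# through exactly the event sequence of the cohort engine with
# pseudo-random draws; by the law of large numbers its per-patient means
# converge to the cohort outputs, giving an independent check of the
# deterministic matrix arithmetic.

#' Microsimulation oracle for the cohort engine
#'
#' @inheritParams run_cohort
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed (local to this call; the global RNG state is
#'   restored on exit).
#' @return A list shaped like a `strategy_outcome` (without trace):
#'   `total_cost`, `total_qaly`, `salvage_rate`, `salvage_operations`,
#'   each a per-patient mean, plus Monte-Carlo standard errors in `se`.
#' @export
run_microsim <- function(strategy = c("navigated", "traditional"),
                         params = default_parameters(),
                         conventions = model_conventions(),
                         n_patients = 10000, seed = 1,
                         include_navigation_cost = TRUE) {
  strategy <- match.arg(strategy)
  stopifnot(n_patients >= 1)
  if (conventions$half_cycle_correction)
    stop("the microsimulation oracle supports occupancy-based accrual only ",
         "(half_cycle_correction = FALSE)", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  cl <- params$clinical; ut <- params$utilities; ec <- params$economics
  r <- ec$discount_rate; horizon <- as.integer(ec$horizon)
  u_fix <- if (strategy == "navigated") ut$u_nav else ut$u_trad
  p_safe <- if (strategy == "navigated") cl$p_safe_nav else cl$p_safe_trad
  f_dying <- conventions$dying_cycle_utility_fraction
  df0 <- if (conventions$discount_cycle_zero) 1 / (1 + r) else 1

  n <- as.integer(n_patients)
  # states: 1 safe, 2 unsafe, 3 salvage, 4 dead
  state <- ifelse(runif(n) < cl$p_periop_death_imn, 4L,
                  ifelse(runif(n) < p_safe, 1L, 2L))
  cost0 <- params$costs$cost_imn
  if (strategy == "navigated" && include_navigation_cost)
    cost0 <- cost0 + nav_cost_per_patient(params$costs)
  cost <- rep(cost0 * df0, n)
  qaly <- if (conventions$initial_utility_accrual)
    (state <= 2L) * u_fix * df0 else numeric(n)
  ever_salvage <- logical(n)
  ever_operation <- logical(n)

  for (t in seq_len(horizon)) {
    df <- (1 + r)^(-t)
    age <- ec$start_age + t - 1L
    qx <- lookup_qx(params$life_table, age)
    pd_fix <- .fix_death_prob(t, qx, params, conventions)

    in_fix <- state <= 2L
    in_salv <- state == 3L
    u_now <- runif(n)
    dies_bg <- (in_fix & u_now < pd_fix) | (in_salv & u_now < qx)
    utility_state <- ifelse(in_fix, u_fix, ifelse(in_salv, ut$u_tha, 0))
    qaly <- qaly + ifelse(dies_bg, f_dying * utility_state * df, 0)
    state[dies_bg] <- 4L

    in_fix <- state <= 2L
    p_fail <- ifelse(state == 1L, cl$annual_fail_safe,
                     ifelse(state == 2L, cl$annual_fail_unsafe, 0))
    fails <- in_fix & (runif(n) < p_fail)
    cost <- cost + fails * params$costs$cost_tha * df
    ever_operation <- ever_operation | fails
    dies_tha <- fails & (runif(n) < cl$p_periop_death_tha)
    qaly <- qaly + ifelse(dies_tha, f_dying * u_fix * df, 0)
    enters <- fails & !dies_tha
    ever_salvage <- ever_salvage | enters
    qaly <- qaly + ifelse(enters, ut$disutility_salvage * df, 0)
    state[dies_tha] <- 4L
    state[enters] <- 3L

    alive_util <- ifelse(state <= 2L, u_fix, ifelse(state == 3L, ut$u_tha, 0))
    qaly <- qaly + alive_util * df
  }

  se <- function(x) stats::sd(x) / sqrt(n)
  structure(list(strategy = strategy,
                 total_cost = mean(cost), total_qaly = mean(qaly),
                 salvage_rate = mean(ever_salvage),
                 salvage_operations = mean(ever_operation),
                 n_patients = n, seed = seed,
                 se = c(cost = se(cost), qaly = se(qaly),
                        salvage_rate = se(as.numeric(ever_salvage)))),
            class = "microsim_outcome")
}

#' @export
print.microsim_outcome <- function(x, ...) {
  cat(sprintf(
    "microsimulation (%s, n = %d): %.3f QALYs (se %.4f), cost %s (se %s), salvage %.2f%%\n",
    x$strategy, x$n_patients, x$total_qaly, x$se[["qaly"]],
    format(round(x$total_cost), big.mark = ","),
    format(round(x$se[["cost"]]), big.mark = ","), 100 * x$salvage_rate))
  invisible(x)
}
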