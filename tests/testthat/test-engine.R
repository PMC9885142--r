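test_that("initial distribution splits perioperative survivors by safe-zone probability", {
  p <- default_parameters()
  nav <- initial_distribution("navigated", p)
  expect_equal(unname(nav), c(0.94 * 0.956, 0.94 * 0.044, 0, 0.06))
  expect_equal(sum(nav), 1)
  trad <- initial_distribution("traditional", p)
  expect_equal(unname(trad), c(0.94 * 0.74, 0.94 * 0.26, 0, 0.06))
  # no perioperative deaths, perfect placement
  q <- quiet_params()
  q$clinical$p_safe_nav <- 1
  expect_equal(unname(initial_distribution("navigated", q)), c(1, 0, 0, 0))
})

test_that("a single cycle does hand-checkable arithmetic", {
  # from a pure safe-fixation cohort with no background mortality:
  # failures 2.7%, of whom 6% die during the salvage THA
  p <- quiet_params()
  p$clinical$annual_fail_safe <- 0.027
  p$clinical$p_periop_death_tha <- 0.06
  st <- c(safe = 1, unsafe = 0, salvage = 0, dead = 0)
  step <- cycle_transition(st, 1, "navigated", p, model_conventions())
  expect_equal(step$new_salvage, 0.027 * 0.94)
  expect_equal(step$salvage_operations, 0.027)
  expect_equal(step$cycle_cost, 0.027 * 108000)
  expect_equal(unname(step$state),
               c(0.973, 0, 0.027 * 0.94, 0.027 * 0.06))
  expect_equal(sum(step$state), 1)
})

test_that("no-event limit leaves the cohort in place and accrues plain utility", {
  p <- quiet_params(economics = list(discount_rate = 0))
  conv <- model_conventions(initial_utility_accrual = FALSE,
                            discount_cycle_zero = FALSE)
  out <- run_cohort("navigated", p, conv)
  expect_equal(out$total_qaly, 5 * 0.82)  # horizon x utility exactly
  expect_equal(out$total_cost, 54000 + nav_cost_per_patient(p$costs))
  expect_equal(out$salvage_rate, 0)
  expect_true(all(abs(out$trace$safe - 0.956 * 1) < 1e-12))
})

test_that("occupancies sum to one each cycle and salvage accumulates monotonically", {
  set.seed(7)
  for (i in 1:20) {
    p <- random_parameter_set()
    conv <- model_conventions(
      first_year_mortality_includes_periop = i %% 2 == 0,
      dying_cycle_utility_fraction = c(0, 0.5, 1)[i %% 3 + 1])
    for (arm in c("navigated", "traditional")) {
      out <- run_cohort(arm, p, conv)
      tr <- out$trace
      expect_true(all(abs(rowSums(tr[, c("safe", "unsafe", "salvage", "dead")]) - 1)
                      < 1e-12))
      expect_true(all(tr[, c("safe", "unsafe", "salvage", "dead")] >= -1e-15))
      expect_true(all(diff(tr$cum_salvage) >= 0))
      expect_lte(out$salvage_rate, 1 - p$clinical$p_periop_death_imn)
      # discounting only shrinks amounts
      expect_true(all(tr$disc_cost <= tr$cycle_cost + 1e-9))
      # salvage occupancy changes only by inflow minus salvage-state deaths
      salvage_deaths <- tr$new_salvage[-1] - diff(tr$salvage)
      expect_true(all(salvage_deaths >= -1e-12))
      expect_true(is.finite(out$total_qaly) && is.finite(out$total_cost))
      expect_lte(out$total_qaly, (p$economics$horizon + 1) * 1)
      expect_gte(out$total_qaly, 0)
    }
  }
})

test_that("QALYs respond monotonically to utility and hazard parameters", {
  set.seed(11)
  conv <- model_conventions()
  for (i in 1:8) {
    p <- random_parameter_set()
    base <- run_cohort("navigated", p, conv, trace = FALSE)$total_qaly
    up <- p; up$utilities$u_nav <- min(1, p$utilities$u_nav + 0.05)
    expect_gte(run_cohort("navigated", up, conv, trace = FALSE)$total_qaly, base)
    # failure only hurts when the salvage state is no better than fixation
    if (p$utilities$u_tha <= p$utilities$u_nav) {
      worse <- p
      worse$clinical$annual_fail_safe <- min(1, p$clinical$annual_fail_safe + 0.05)
      worse$clinical$annual_fail_unsafe <-
        max(worse$clinical$annual_fail_unsafe, worse$clinical$annual_fail_safe)
      expect_lte(run_cohort("navigated", worse, conv, trace = FALSE)$total_qaly,
                 base)
    }
    deadlier <- p
    deadlier$clinical$p_death_first_year <-
      min(1, p$clinical$p_death_first_year + 0.1)
    expect_lte(run_cohort("navigated", deadlier, conv, trace = FALSE)$total_qaly,
               base)
  }
})

test_that("arms coincide when their distinguishing parameters are equalized", {
  p <- default_parameters()
  p$clinical$p_safe_trad <- p$clinical$p_safe_nav
  p$utilities$u_trad <- p$utilities$u_nav
  nav <- run_cohort("navigated", p, include_navigation_cost = FALSE)
  trad <- run_cohort("traditional", p)
  expect_equal(nav$total_cost, trad$total_cost)
  expect_equal(nav$total_qaly, trad$total_qaly)
  expect_equal(nav$salvage_rate, trad$salvage_rate)
})

test_that("cohort traces export to CSV", {
  out <- run_cohort("traditional", default_parameters())
  path <- tempfile(fileext = ".csv")
  write_trace(out, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 6)
  expect_true(all(c("cycle", "age", "safe", "unsafe", "salvage", "dead",
                    "disc_cost", "disc_qaly", "new_salvage", "cum_salvage")
                  %in% names(back)))
  expect_equal(back$cum_salvage[6], out$salvage_rate)
})
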