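test_that("calibration recovers a known generating configuration from synthetic anchors", {
  truth_conv <- model_conventions(first_year_mortality_includes_periop = TRUE,
                                  initial_utility_accrual = TRUE,
                                  discount_cycle_zero = FALSE)
  truth_q <- 0.041
  truth_amort <- 4.2
  p <- default_parameters(costs = list(amortization_years = truth_amort),
                          life_table = flat_life_table(truth_q, 70:80))
  nav <- run_cohort("navigated", p, truth_conv, trace = FALSE)
  trad <- run_cohort("traditional", p, truth_conv, trace = FALSE)
  anchors <- calibration_anchors(navigated_qaly = nav$total_qaly,
                                 traditional_qaly = trad$total_qaly,
                                 navigated_cost = nav$total_cost)
  cal <- calibrate_model(anchors)
  expect_identical(cal$conventions$first_year_mortality_includes_periop, TRUE)
  expect_identical(cal$conventions$initial_utility_accrual, TRUE)
  expect_identical(cal$conventions$discount_cycle_zero, FALSE)
  expect_lt(abs(cal$q_background - truth_q), 1e-4)
  expect_equal(cal$amortization_years, truth_amort, tolerance = 1e-3)
  expect_lt(max(abs(cal$residuals)), 1e-6)
})

test_that("degenerate anchors produce a calibration-failure report, not a silent fit", {
  bad <- calibration_anchors(navigated_qaly = 3.0, traditional_qaly = 3.0)
  cal <- calibrate_conventions(bad)
  expect_false(cal$converged)
  expect_error(calibrate_model(bad), "calibration failure")
  expect_warning(calibrate_model(bad, allow_failure = TRUE), "calibration failure")
})

test_that("shipped calibration constants are exactly what calibrate_model() produces", {
  cal <- calibrated_fixture()
  k <- calibrated_constants()
  expect_true(cal$converged)
  expect_equal(cal$q_background, k$q_background, tolerance = 1e-6)
  expect_equal(cal$amortization_years, k$amortization_years, tolerance = 1e-6)
  expect_equal(unclass(cal$conventions)[names(k$conventions)], k$conventions)
  # and default_parameters()/model_conventions() run straight off them
  p <- default_parameters()
  expect_equal(unique(p$life_table$qx), k$q_background)
  expect_equal(p$costs$amortization_years, k$amortization_years)
})

test_that("the amortization back-out is consistent and flags degenerate anchors", {
  cal <- calibrated_fixture()
  # the calibrated parameters reproduce the navigated cost anchor exactly
  nav <- run_cohort("navigated", cal$params, cal$conventions, trace = FALSE)
  expect_equal(nav$total_cost, cal$anchors$navigated_cost, tolerance = 1e-9)
  # a cost anchor with no room for navigation -> infinite amortization
  nav0 <- run_cohort("navigated", cal$params, cal$conventions,
                     include_navigation_cost = FALSE, trace = FALSE)
  a0 <- calibrate_amortization(
    calibration_anchors(navigated_cost = nav0$total_cost),
    cal$params, cal$conventions)
  expect_identical(a0$amortization_years, Inf)
  expect_error(calibrate_amortization(
    calibration_anchors(navigated_cost = nav0$total_cost - 1000),
    cal$params, cal$conventions), "negative")
})

test_that("any two points of the inverse-volume line predict the third", {
  cal <- calibrated_fixture()
  vc <- icer_vs_volume(cal$params, c(100, 200, 300), cal$conventions)
  # structural: fit A + B/V through two volumes, predict the third
  A <- (vc$icers[2] * 2 - vc$icers[1]) # from V=100,200: A = 2*I200 - I100
  B <- (vc$icers[1] - vc$icers[2]) * 200
  expect_equal(A + B / 300, vc$icers[3], tolerance = 1e-9)
  # the slope cross-check reports the annualized navigation cost implied
  # by a reference ICER-by-volume table
  ref <- data.frame(volume = c(100, 200, 300), icer = vc$icers)
  am <- calibrate_amortization(cal$anchors, cal$params, cal$conventions,
                               reference_icers = ref)
  expect_equal(am$slope_implied_annualized, cal$annualized_cost,
               tolerance = 1e-6)
})
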