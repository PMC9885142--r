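test_that("the volume curve follows the closed inverse-volume form exactly", {
  p <- default_parameters()
  vols <- c(60, 100, 137, 200, 300, 450)
  vc <- icer_vs_volume(p, vols)
  # direct evaluation at each volume must sit on A + B/V
  direct <- vapply(vols, function(v) {
    p$costs$annual_volume <- v
    nav <- run_cohort("navigated", p, trace = FALSE)
    trad <- run_cohort("traditional", p, trace = FALSE)
    icer(nav, trad)$icer
  }, numeric(1))
  expect_equal(vc$icers, direct, tolerance = 1e-9)
  expect_equal(vc$icers, vc$A + vc$B / vols, tolerance = 1e-12)
  expect_true(all(diff(vc$icers) < 0))  # strictly decreasing in volume
  expect_equal(vc$direction, "negative")
  # equal-spacing identity of the 1/V law
  i3 <- icer_vs_volume(p, c(100, 200, 300))$icers
  expect_equal((i3[1] - i3[2]) / (i3[2] - i3[3]), 3, tolerance = 1e-9)
  # no navigation cost -> flat curve
  pfree <- default_parameters(costs = list(nav_purchase = 0))
  vcf <- icer_vs_volume(pfree, vols)
  expect_equal(diff(range(vcf$icers)), 0)
  expect_equal(vcf$direction, "flat")
})

test_that("one-way sweeps classify directions as the model implies", {
  p <- default_parameters()
  expect_equal(one_way_dsa(p, "p_safe_trad")$direction, "positive")
  expect_equal(one_way_dsa(p, "annual_fail_safe")$direction, "positive")
  expect_equal(one_way_dsa(p, "u_tha")$direction, "positive")
  # the salvage THA price is twice the IMN price, so a costlier IMN makes
  # salvage avoidance more valuable: negative relationship
  expect_equal(one_way_dsa(p, "cost_imn")$direction, "negative")
  expect_equal(one_way_dsa(p, "annual_fail_unsafe")$direction, "negative")
  expect_equal(one_way_dsa(p, "disutility_salvage")$direction, "flat")
  expect_equal(one_way_dsa(p, "p_periop_death_imn")$direction, "flat")
  # without the price tie the IMN cost cancels between arms entirely
  ow <- one_way_dsa(p, "cost_imn", tie_tha_cost = FALSE)
  expect_equal(ow$direction, "flat")
  expect_lt(ow$span, 1e-12)
  expect_error(one_way_dsa(p, "p_safe_nav", range = c(0.5, 1.2)), "domain")
  expect_error(one_way_dsa(p, "not_a_parameter"), "unknown")
})

test_that("threshold searches solve to the WTP and respect brackets", {
  p <- default_parameters()
  th <- threshold_search(p, "annual_volume", bracket = c(50, 300))
  expect_false(th$no_solution)
  expect_equal(th$direction, "greater_than")
  expect_lt(abs(th$icer_at_threshold - 140000), 1)
  # substituting the solved volume back reproduces ICER = WTP
  p2 <- p; p2$costs$annual_volume <- th$threshold
  nav <- run_cohort("navigated", p2, trace = FALSE)
  trad <- run_cohort("traditional", p2, trace = FALSE)
  expect_lt(abs(icer(nav, trad)$icer - 140000), 1)

  th_p <- threshold_search(p, "p_safe_nav", volume = 200,
                           bracket = c(0.3, 0.9999))
  expect_false(th_p$no_solution)
  expect_lt(abs(th_p$icer_at_threshold - 140000), 1)

  # purchase-cost threshold scales linearly with volume (1/V allocation)
  th_c200 <- threshold_search(p, "nav_purchase", volume = 200,
                              bracket = c(1e5, 5e7))
  th_c100 <- threshold_search(p, "nav_purchase", volume = 100,
                              bracket = c(1e5, 5e7))
  expect_equal(th_c200$threshold / th_c100$threshold, 2, tolerance = 1e-4)
  expect_equal(th_c200$direction, "less_than")
})

test_that("an unreachable bracket returns the no-solution sentinel", {
  p <- default_parameters()
  # at 100 cases/year even perfect placement is not cost-effective
  th <- threshold_search(p, "p_safe_nav", volume = 100,
                         bracket = c(0.74, 0.9999))
  expect_true(th$no_solution)
  expect_true(is.na(th$threshold))
})

test_that("two-way classification is monotone in cost and placement probability", {
  p <- default_parameters()
  tw <- two_way_dsa(p, cost_range = c(2e6, 2.2e7),
                    probability_range = c(0.74, 1), grid_size = 9)
  # base case cell: default purchase cost at default probability, V = 200
  i <- which.min(abs(tw$nav_purchase - 7e6))
  j <- which.min(abs(tw$p_safe_nav - 0.956))
  expect_true(tw$navigated_ce[i, j])
  # cheaper systems can only help; better placement can only help
  for (j in seq_along(tw$p_safe_nav))
    expect_true(all(diff(tw$navigated_ce[, j]) <= 0))
  for (i in seq_along(tw$nav_purchase))
    expect_true(all(diff(tw$navigated_ce[i, ]) >= 0))
})

test_that("the tornado table ranks parameters by ICER span", {
  p <- default_parameters()
  tor <- tornado_summary(p, parameters = c("p_safe_trad", "u_tha",
                                           "disutility_salvage"))
  expect_equal(tor$parameter[1], "p_safe_trad")
  expect_true(all(diff(tor$span) <= 0))
})
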