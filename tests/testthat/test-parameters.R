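test_that("odds-ratio conversion matches odds-space arithmetic and known values", {
  # outside-zone failure rate from the inside-zone baseline and pooled OR
  expect_equal(round(or_to_probability(0.027, 2.94), 4), 0.0754)
  expect_equal(round(100 * or_to_probability(0.027, 2.94), 1), 7.5)
  # odds 1 -> odds 3 -> p = 3/4
  expect_equal(or_to_probability(0.5, 3), 0.75)
  # identity odds ratio and exact odds-space equivalence
  p0 <- seq(0.01, 0.95, by = 0.07)
  expect_equal(or_to_probability(p0, 1), p0)
  for (or in c(0.3, 1.7, 2.94, 8)) {
    odds1 <- or * p0 / (1 - p0)
    expect_equal(or_to_probability(p0, or), odds1 / (1 + odds1),
                 tolerance = 1e-14)
  }
  # monotone in both arguments
  expect_true(all(diff(or_to_probability(p0, 2.94)) > 0))
  expect_true(or_to_probability(0.027, 3) > or_to_probability(0.027, 2.9))
  expect_error(or_to_probability(1, 2), "odds are undefined")
  expect_error(or_to_probability(0.1, 0), "positive")
})

test_that("HHS-to-utility map interpolates through the published anchors", {
  expect_equal(hhs_to_utility(86.7), 0.82)
  expect_equal(hhs_to_utility(82.7), 0.79)
  expect_equal(hhs_to_utility(84.7), 0.805)  # midpoint of a linear map
  # extrapolation stays linear
  expect_equal(hhs_to_utility(90.7), 0.85)
  expect_error(hhs_to_utility(80, matrix(c(85, 0.8, 85, 0.7), 2, byrow = TRUE)),
               "distinct")
})

test_that("beta moment fitting reproduces published shapes and round-trips", {
  b <- fit_beta_moments(0.027, 0.0027)
  expect_equal(b$shape1, 97.27, tolerance = 1e-3)
  expect_equal(b$shape2, 3505.43, tolerance = 1e-3)
  b2 <- fit_beta_moments(0.956, 0.0956)
  expect_equal(b2$shape1, 3.44, tolerance = 0.01)
  expect_equal(b2$shape2, 0.16, tolerance = 0.01)
  u <- fit_beta_moments(0.5, 0.2887)  # uniform moments
  expect_equal(u$shape1, 1, tolerance = 1e-3)
  expect_equal(u$shape2, 1, tolerance = 1e-3)
  expect_error(fit_beta_moments(0.5, 0.5), "infeasible")
  expect_error(fit_beta_moments(1.2, 0.1), "mean")

  # moment round-trip to 6 significant figures across the shape range
  set.seed(42)
  for (i in 1:50) {
    a <- 10^runif(1, log10(0.05), 4); bb <- 10^runif(1, log10(0.05), 4)
    m <- dist_moments("beta", a, bb)
    fit <- fit_beta_moments(m[["mean"]], m[["sd"]])
    expect_equal(fit$shape1, a, tolerance = 1e-6)
    expect_equal(fit$shape2, bb, tolerance = 1e-6)
  }
})

test_that("gamma moment fitting (rate parameterization) reproduces published shapes", {
  g <- fit_gamma_moments(54000, 37000)
  expect_equal(g$shape1, 2.13, tolerance = 1e-3)
  expect_equal(g$shape2, 3.9e-5, tolerance = 0.02)
  g2 <- fit_gamma_moments(108000, 10800)
  expect_equal(g2$shape1, 100)
  expect_equal(g2$shape2, 0.00093, tolerance = 0.005)
  expect_equal(fit_gamma_moments(5, 5)$shape1, 1)  # exponential
  expect_error(fit_gamma_moments(-1, 1), "positive")

  set.seed(43)
  for (i in 1:50) {
    a <- 10^runif(1, log10(0.05), 4); r <- 10^runif(1, -6, 2)
    m <- dist_moments("gamma", a, r)
    fit <- fit_gamma_moments(m[["mean"]], m[["sd"]])
    expect_equal(fit$shape1, a, tolerance = 1e-6)
    expect_equal(fit$shape2, r, tolerance = 1e-6)
  }
})

test_that("published PSA shapes are consistent with their quoted moments", {
  d <- psa_distributions()
  # all rows except THA utility agree within 3% relative error
  for (nm in setdiff(names(d), "u_tha")) {
    m <- dist_moments(d[[nm]]$family, d[[nm]]$shape1, d[[nm]]$shape2)
    expect_equal(m[["mean"]], d[[nm]]$mean, tolerance = 0.03, label = nm)
    expect_equal(m[["sd"]], d[[nm]]$sd, tolerance = 0.03, label = nm)
  }
  # the THA-utility Beta(3999.4, 2666.3) implies sd 0.006, a tenth of the
  # quoted 0.06 - a documented inconsistency in the source table
  m <- dist_moments("beta", 3999.4, 2666.3)
  expect_equal(m[["mean"]], 0.6, tolerance = 1e-4)
  expect_equal(m[["sd"]], 0.006, tolerance = 0.01)
})

test_that("navigation cost allocation is inverse in volume and linear in purchase", {
  co <- default_parameters()$costs
  co100 <- co; co100$annual_volume <- 100
  co200 <- co; co200$annual_volume <- 200
  expect_equal(nav_cost_per_patient(co200), nav_cost_per_patient(co100) / 2)
  co0 <- co; co0$nav_purchase <- 0
  expect_equal(nav_cost_per_patient(co0), 0)
  co2x <- co; co2x$nav_purchase <- 2 * co$nav_purchase
  expect_equal(nav_cost_per_patient(co2x), 2 * nav_cost_per_patient(co))
  co_bad <- co; co_bad$annual_volume <- 0
  expect_error(nav_cost_per_patient(co_bad), "positive")
})

test_that("parameter construction validates and supports overrides", {
  p <- default_parameters()
  expect_s3_class(p, "imn_parameters")
  expect_equal(p$clinical$p_safe_nav, 0.956)
  expect_equal(p$utilities$u_tha, 0.6)
  p2 <- default_parameters(economics = list(wtp = 280000))
  expect_equal(p2$economics$wtp, 280000)
  expect_equal(p2$clinical$p_safe_nav, 0.956)
  expect_error(default_parameters(clinical = list(p_safe_nav = 1.2)),
               "p_safe_nav")
  expect_error(default_parameters(clinical = list(nonsense = 1)), "unknown")
  expect_error(default_parameters(bogus_group = list(a = 1)), "unknown")
})

test_that("configurations load from YAML and JSON with defaults filled in", {
  cfg <- list(economics = list(wtp = 280000),
              costs = list(annual_volume = 300))
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  p <- load_parameters(yml)
  expect_equal(p$economics$wtp, 280000)
  expect_equal(p$costs$annual_volume, 300)
  expect_equal(p$clinical$p_safe_nav, 0.956)  # default retained
  prov <- attr(p, "provenance")
  expect_equal(unname(prov[c("economics", "clinical")]), c("user", "default"))

  jsn <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jsn, auto_unbox = TRUE)
  expect_equal(load_parameters(jsn)$economics$wtp, 280000)

  # life table via CSV path relative to the config
  lt_file <- tempfile(fileext = ".csv")
  write_life_table(gompertz_life_table(0.02, 0.1, 70:76), lt_file)
  yaml::write_yaml(list(life_table = lt_file), yml)
  p3 <- load_parameters(yml)
  expect_equal(nrow(p3$life_table), 7)
  expect_equal(p3$life_table$qx[1], 0.02)

  expect_equal(load_parameters(list())$economics$wtp, 140000)
})
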