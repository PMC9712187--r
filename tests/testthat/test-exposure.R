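test_that("moment matching reproduces the requested mean and SD", {
  d <- fit_exposure(19.4, 8.7)
  expect_equal(d$meanlog, 2.8737, tolerance = 1e-4)
  expect_equal(d$sdlog, 0.4281, tolerance = 1e-4)
  # round-trip through the (untruncated) fitted density by numerical
  # integration, an independent check of the closed-form parametrisation
  m1 <- integrate(function(x) x * dlnorm(x, d$meanlog, d$sdlog), 0, Inf,
                  rel.tol = 1e-10)$value
  m2 <- integrate(function(x) x^2 * dlnorm(x, d$meanlog, d$sdlog), 0, Inf,
                  rel.tol = 1e-10)$value
  expect_equal(m1, 19.4, tolerance = 1e-6)
  expect_equal(sqrt(m2 - m1^2), 8.7, tolerance = 1e-6)
  # property across parameter space (0.1% relative tolerance)
  for (p in list(c(13, 5), c(21, 9.5), c(5, 6), c(40, 10))) {
    dd <- fit_exposure(p[1], p[2])
    mm <- integrate(function(x) x * dlnorm(x, dd$meanlog, dd$sdlog), 0, Inf,
                    rel.tol = 1e-10)$value
    expect_equal(mm, p[1], tolerance = 1e-3)
  }
})

test_that("truncated density integrates to one", {
  for (p in list(c(19.4, 8.7), c(13, 10), c(45, 30))) {
    d <- fit_exposure(p[1], p[2])
    mass <- integrate(function(x) exp_density(d, x), 0, d$upper,
                      rel.tol = 1e-9)$value
    expect_equal(mass, 1, tolerance = 1e-6)
  }
})

test_that("degenerate and invalid inputs are handled", {
  expect_equal(fit_exposure(19.4, 0), point_mass(19.4))
  expect_error(fit_exposure(0, 1), "between 0 and 100")
  expect_error(fit_exposure(100, 1), "between 0 and 100")
  expect_error(fit_exposure(20, -1), "non-negative")
  expect_error(exp_density(point_mass(5), 5), "no density")
})

test_that("quantile cut-points invert the CDF", {
  d <- fit_exposure(19.4, 8.7)
  q20 <- quintile_cutpoint(d, 0.2)
  expect_equal(q20, exp(2.8737 - 0.8416 * 0.4281), tolerance = 1e-3)
  expect_equal(exp_cdf(d, q20), 0.2, tolerance = 1e-9)
  expect_equal(quintile_cutpoint(point_mass(19.4), 0.2), 19.4)
  expect_error(exp_quantile(d, 1.2), "between 0 and 1")
})

test_that("proportional reduction scales the mean and preserves the CV", {
  d <- fit_exposure(18, 8)
  r <- 0.3
  cf <- apply_scenario(d, scenario_reduction(r))
  expect_equal(cf$sdlog, d$sdlog)            # CV unchanged
  expect_equal(exp_mean(cf) / exp_mean(d), 1 - r, tolerance = 1e-9)
  expect_equal(apply_scenario(point_mass(20), scenario_reduction(0.1)),
               point_mass(18))
  # identity and full-elimination limits
  expect_equal(apply_scenario(d, scenario_reduction(0)), d)
  expect_equal(apply_scenario(d, scenario_reduction(1)), point_mass(0))
  expect_equal(apply_scenario(d, scenario_baseline()), d)
  expect_error(scenario_reduction(1.2), "\\[0, 1\\]")
})

test_that("first-quintile shift truncates, renormalises and is dominated", {
  d <- fit_exposure(19.4, 8.7)
  cut <- quintile_cutpoint(d, 0.2)
  cf <- apply_scenario(d, scenario_quintile())
  expect_equal(cf$upper, cut)
  mass <- integrate(function(x) exp_density(cf, x), 0, cf$upper,
                    rel.tol = 1e-9)$value
  expect_equal(mass, 1, tolerance = 1e-6)
  # stochastic dominance: counterfactual CDF everywhere >= baseline CDF
  xs <- seq(0.5, 99.5, by = 0.5)
  expect_true(all(exp_cdf(cf, xs) - exp_cdf(d, xs) >= -1e-12))
  # point-mass reading sits at the bottom-quintile mean, below the cut
  pm <- apply_scenario(d, scenario_quintile(method = "point_mass"))
  expect_equal(pm$family, "point_mass")
  expect_lt(pm$location, cut)
  expect_equal(apply_scenario(point_mass(12), scenario_quintile()),
               point_mass(12))
})
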