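test_that("with all perturbations off every draw equals the deterministic run", {
  res <- run_monte_carlo(tiny_exposure(), tiny_events(),
                         scenarios = default_scenarios(),
                         config = mc_config(n_draws = 25, seed = 3,
                                            perturb = character(0)))
  s <- res$summary
  expect_equal(s$median, s$estimate, tolerance = 1e-9)
  expect_equal(s$ui_low, s$ui_high)    # zero-width intervals
  expect_equal(s$ui_low, s$median)
})

test_that("the simulation is a pure function of the seed", {
  cfg <- mc_config(n_draws = 120, seed = 42)
  r1 <- run_monte_carlo(tiny_exposure(), tiny_events(), config = cfg)
  r2 <- run_monte_carlo(tiny_exposure(), tiny_events(), config = cfg)
  expect_identical(r1$summary, r2$summary)
  r3 <- run_monte_carlo(tiny_exposure(), tiny_events(),
                        config = mc_config(n_draws = 120, seed = 43))
  expect_false(identical(r3$summary$median, r1$summary$median))
})

test_that("uncertainty intervals bracket the median in every cell", {
  res <- run_monte_carlo(tiny_exposure(), tiny_events(),
                         config = mc_config(n_draws = 200, seed = 9))
  s <- res$summary
  expect_true(all(s$ui_low <= s$median + 1e-12))
  expect_true(all(s$median <= s$ui_high + 1e-12))
  # median consistent with the deterministic estimate under near-symmetric
  # input perturbations
  cvd <- s[s$outcome == "CVD" & s$sex == "total" &
           s$scenario == "attributable", ]
  expect_equal(cvd$median, cvd$estimate, tolerance = 0.05)
})

test_that("empirical quantiles match analytic ones for a single perturbed input", {
  ex <- tiny_exposure()[1, ]
  ev <- tiny_events(ex)
  res <- run_monte_carlo(ex, ev, scenarios = list(),
                         config = mc_config(n_draws = 5e4, seed = 77,
                                            perturb = "events"),
                         keep_draws = TRUE)
  s <- res$summary
  row <- which(s$outcome == "CHD" & s$sex == "male" & s$metric == "deaths")
  pif <- s$estimate[row] / ev$value[ev$outcome == "CHD" &
                                    ev$metric == "deaths"]
  # attributable draws are pif * E with E ~ Normal(v, (ui width)/3.92)
  # truncated at 0 (truncation negligible here)
  v <- ev$value[ev$outcome == "CHD" & ev$metric == "deaths"]
  sd <- (1.2 - 0.8) * v / (2 * qnorm(0.975))
  expect_equal(s$ui_low[row], pif * (v - qnorm(0.975) * sd),
               tolerance = 0.005)
  expect_equal(s$ui_high[row], pif * (v + qnorm(0.975) * sd),
               tolerance = 0.005)
  expect_equal(s$median[row], pif * v, tolerance = 0.005)
})

test_that("perturbation flags demand their uncertainty inputs", {
  ex <- tiny_exposure()
  ex$se_mean_pct <- NULL
  expect_error(run_monte_carlo(ex, tiny_events(),
                               config = mc_config(10, 1, "intake")),
               "se_mean_pct")
  ev <- tiny_events()
  ev$ui_low[2] <- NA
  expect_error(run_monte_carlo(tiny_exposure(), ev,
                               config = mc_config(10, 1, "events")),
               "ui_low")
  expect_error(mc_config(perturb = "banana"), "unknown perturbation")
  expect_error(mc_config(n_draws = 0), "at least 1")
})

test_that("sensitivity analysis moves in the direction implied by the model", {
  ex <- tiny_exposure(); ev <- tiny_events()
  sens <- list(
    null = sensitivity_scenario("null", rr_multiplier = 1),
    up = sensitivity_scenario("up", rr_multiplier = 1.1),
    down = sensitivity_scenario("down", rr_multiplier = 0.9),
    tm12 = sensitivity_scenario("tm12", x_tmrel = 12))
  expect_warning(out <- run_sensitivity(ex, ev, sens = sens),
                 "does not alter")
  expect_equal(out$pct_change[out$label == "null"], rep(0, 3))
  # PIF is monotone in RR: higher RR -> more attributable events
  expect_true(all(out$pct_change[out$label == "up"] > 0))
  expect_true(all(out$pct_change[out$label == "down"] < 0))
  # raising the TMREL flattens the low-exposure segment; cross-check the
  # resulting PAF against the independent oracle
  ded <- compute_burden(ex, ev,
                        rr_specs = list(CHD = rr_spec("CHD", 1.29,
                                                      x_tmrel = 12),
                                        stroke = rr_spec("stroke", 1.34,
                                                         x_tmrel = 12)),
                        scenarios = list())
  got <- ded$pif[ded$sex == "male" & ded$outcome == "CHD"][1]
  want <- oracle_pif(1.29, 22, 12, ex$mean_pct[1], ex$sd_pct[1])
  expect_equal(got, want, tolerance = 1e-4)
  alt_total <- out$alternative[out$label == "tm12" & out$metric == "deaths"]
  base_total <- out$primary[out$label == "tm12" & out$metric == "deaths"]
  expect_true(alt_total != base_total)
})

test_that("sensitivity scenarios allow exactly one perturbation family", {
  expect_error(sensitivity_scenario("x", x_tmrel = 10, rr_multiplier = 1.1),
               "not both")
  expect_error(sensitivity_scenario("x"), "specify")
  expect_error(sensitivity_scenario("x", rr_multiplier = -1), "positive")
})
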