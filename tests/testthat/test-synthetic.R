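test_that("the default bundle has the advertised structure", {
  b <- the_bundle()
  expect_equal(nrow(b$exposure), 16L)
  expect_equal(nrow(b$events), 96L)   # 16 strata x 2 outcomes x 3 metrics
  expect_silent(validate_exposure_table(b$exposure))
  expect_silent(validate_event_table(b$events))
  # intake means decline linearly from 21 to 13 with age, same for each sex
  m <- b$exposure$mean_pct[b$exposure$sex == "male"]
  expect_equal(m, seq(21, 13, length.out = 8))
  expect_equal(b$exposure$sd_pct, 0.45 * b$exposure$mean_pct)
  # event counts rise with age within each sex/outcome/metric series
  deaths <- b$events[b$events$metric == "deaths" & b$events$sex == "male" &
                     b$events$outcome == "CHD", ]
  expect_true(all(diff(deaths$value[order(deaths$age_group)]) > 0))
})

test_that("the generator is deterministic given its configuration", {
  b1 <- generate_study(synthetic_config(oracle_step = 0.01))
  b2 <- generate_study(synthetic_config(oracle_step = 0.01))
  expect_identical(b1, b2)
})

test_that("config validation rejects invalid ranges", {
  expect_error(synthetic_config(n_age_groups = 9), "between 1 and 8")
  expect_error(synthetic_config(mean_young = 0), "\\(0, 100\\)")
  expect_error(synthetic_config(cv = -0.1), "non-negative")
  expect_error(synthetic_config(ui_relative_width = 1), "\\[0, 1\\)")
  expect_error(synthetic_config(chd_death_rate = 0), "positive")
})

test_that("with CV 0 the pipeline matches the closed form exactly", {
  cfg <- synthetic_config(cv = 0, se_relative = 0, oracle_step = 0.01)
  b <- generate_study(cfg)
  cells <- compute_burden(b$exposure, b$events, b$rr_specs,
                          cfg$scenarios)
  # hand computation: point-mass PAF = 1 - 1/RR(x0), reduction PIF =
  # 1 - RR((1-r) x0)/RR(x0)
  specs <- b$rr_specs
  for (i in seq_len(nrow(cells))) {
    sp <- specs[[cells$outcome[i]]]
    cv <- build_rr_curve(sp)
    x0 <- b$exposure$mean_pct[b$exposure$sex == cells$sex[i] &
                              b$exposure$age_group == cells$age_group[i]]
    want <- switch(cells$scenario[i],
      attributable = 1 - 1 / rr_at(cv, x0),
      reduce_10 = 1 - rr_at(cv, 0.9 * x0) / rr_at(cv, x0),
      reduce_20 = 1 - rr_at(cv, 0.8 * x0) / rr_at(cv, x0),
      reduce_50 = 1 - rr_at(cv, 0.5 * x0) / rr_at(cv, x0),
      first_quintile = 0)
    expect_equal(cells$pif[i], want, tolerance = 1e-12)
  }
  # identity scenario averts nothing; full elimination averts everything
  idcells <- compute_burden(b$exposure, b$events, b$rr_specs,
                            list(same = scenario_baseline(),
                                 all = scenario_reduction(1)))
  expect_equal(idcells$averted[idcells$scenario == "same"],
               rep(0, sum(idcells$scenario == "same")))
  expect_equal(idcells$averted[idcells$scenario == "all"],
               idcells$averted[idcells$scenario == "attributable"],
               tolerance = 1e-12)
})

test_that("the pipeline recovers the oracle ground truth", {
  rc <- recovery_check(the_bundle())
  expect_lt(rc$max_rel_err, 1e-4)
  expect_true(rc$pass)
})

test_that("averted fractions fall near 11/21/52% under 10/20/50% reductions", {
  tt <- the_bundle()$truth$totals
  att <- tt$averted[tt$scenario == "attributable" & tt$metric == "deaths"]
  dd <- tt[tt$metric == "deaths", ]
  got <- 100 * dd$averted[match(c("reduce_10", "reduce_20", "reduce_50"),
                                dd$scenario)] / att
  expect_lt(abs(got[1] - 11), 2)
  expect_lt(abs(got[2] - 21), 2)
  expect_lt(abs(got[3] - 52), 2)
})

test_that("bundles round-trip through the delimited formats", {
  b <- generate_study(synthetic_config(n_age_groups = 2, oracle_step = 0.01))
  dir <- withr::local_tempdir()
  write_study(b, dir)
  ex <- read_exposure_table(file.path(dir, "exposure.csv"))
  ev <- read_event_table(file.path(dir, "events.csv"))
  rr <- read_rr_table(file.path(dir, "rr.csv"))
  expect_equal(ex, b$exposure, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ev, b$events, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rr$CHD$rr, 1.29)
  expect_equal(rr$stroke$ci_high, 1.68)
})
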