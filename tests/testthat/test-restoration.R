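rates <- make_rates()

test_that("survival schedules hit the printed decadal endpoints", {
  expect_equal(survival_schedule("fixed"), rep(0.60, 7))
  inc <- survival_schedule("increasing")
  dec <- survival_schedule("decreasing")
  expect_equal(inc[7], 0.60 * 0.95^6)
  expect_equal(round(inc[7], 2), 0.44)
  expect_equal(dec[7], 0.60 * 1.05^6)
  expect_equal(round(dec[7], 2), 0.80)
  # mortality across modes at the last decade spans 20-56%
  mort <- 1 - c(dec[7], 0.60, inc[7])
  expect_equal(round(range(mort), 2), c(0.20, 0.56))
  # survival is clamped at 1
  expect_true(all(survival_schedule("decreasing", s0 = 0.95,
                                    decades = 10) <= 1))
  expect_error(survival_schedule("fixed", decades = 0), ">= 1")
})

test_that("decadal survival composes colony survival and
           fragmentation", {
  comp <- compose_decadal_survival()
  expect_equal(comp$net, 0.58)
  expect_equal(comp$rounded, 0.60)
})

test_that("the cohort model reproduces the fixed-mortality cover peaks", {
  for (case in list(list(n = 500000, peak = 42.4),
                    list(n = 250000, peak = 21.2),
                    list(n = 100000, peak = 8.5))) {
    traj <- project_cover(population_scenario(case$n))
    expect_equal(round(100 * max(traj$added_cover), 1), case$peak)
    expect_equal(traj$year[which.max(traj$added_cover)], 2050)
  }
  # monotone decline after the 2050 peak
  traj <- project_cover(population_scenario(500000))
  after <- traj$added_cover[traj$year >= 2050]
  expect_true(all(diff(after) < 0))
  # surviving fraction never increases
  expect_true(all(diff(traj$surviving_fraction) <= 0))
})

test_that("cover is linear in the number of outplants", {
  unit <- project_cover(population_scenario(1))
  for (mode in c("fixed", "increasing", "decreasing")) {
    u <- project_cover(population_scenario(1, mortality_mode = mode))
    n <- project_cover(population_scenario(321000,
                                           mortality_mode = mode))
    expect_equal(n$added_cover, 321000 * u$added_cover)
  }
  zero <- project_cover(population_scenario(0))
  expect_equal(zero$added_cover, rep(0, 7))
})

test_that("reduced mortality with 500k outplants keeps >= 30% cover at
           2100", {
  traj <- project_cover(population_scenario(
    500000, mortality_mode = "decreasing"))
  expect_gte(traj$added_cover[traj$year == 2100], 0.30)
})

test_that("the stochastic per-colony model converges on the cohort
           model", {
  certain <- population_scenario(1000, base_survival = 1)
  mc <- mc_population_oracle(certain, n_replicates = 3, seed = 1)
  expect_equal(mc$mean_cover, project_cover(certain)$added_cover)
  expect_equal(mc$sd_cover, rep(0, 7))

  sc <- population_scenario(10000)
  mc <- mc_population_oracle(sc, n_replicates = 200, seed = 42)
  det <- project_cover(sc)
  tol <- 3 * mc$sd_cover / sqrt(200)
  expect_true(all(abs(mc$mean_cover - det$added_cover) <= tol))
  # determinism contract
  mc2 <- mc_population_oracle(sc, n_replicates = 200, seed = 42)
  expect_identical(mc, mc2)
})

test_that("restored budgets add uncorrected production and recompute the
           accretion chain", {
  cs <- make_site(c(acropora_palmata = 1, dead_coral = 5, sand = 4))
  base <- site_budget(cs, rates)
  same <- restored_budget(base, 0, rates)
  expect_equal(same$accretion, base$accretion)

  # +30% on a zero-coral, zero-bioerosion site: closed-form chain
  bare <- site_budget(make_site(c(sand = 10)), rates)
  r30 <- restored_budget(bare, 0.30, rates)
  expect_equal(r30$net, 0.30 * 29.07)
  expect_equal(r30$density, 1450)
  expect_equal(r30$accretion, (8721 / 1450) * 100 / 49)

  # strictly increasing in added cover
  deltas <- seq(0.05, 0.30, by = 0.05)
  accs <- vapply(deltas, function(d) {
    restored_budget(base, d, rates)$accretion
  }, numeric(1))
  expect_true(all(diff(accs) > 0))

  full <- site_budget(make_site(c(acropora_palmata = 8, sand = 2)),
                      rates)
  expect_error(restored_budget(full, 0.30, rates), "past 100%")
  expect_error(restored_budget(base, 0.31, rates), "0.30")
})

test_that("substrate deduction lowers endolithic erosion after
           restoration", {
  cs <- make_site(c(acropora_palmata = 1, dead_coral = 5, sand = 4))
  base <- site_budget(cs, rates)
  kept <- restored_budget(base, 0.20, rates)
  ded <- restored_budget(base, 0.20, rates, deduct_substrate = TRUE)
  expect_equal(kept$macro, base$macro)
  expect_equal(ded$macro, (0.5 - 0.2) * 0.4)
  expect_gt(ded$accretion, kept$accretion)
})

test_that("keep-pace verdicts compare cumulative accretion with
           cumulative rise", {
  sc <- slr_scenarios()
  kp <- keep_pace(7.38, sc)
  low <- kp[kp$scenario == "Low" & kp$year == 2100, ]
  expect_equal(round(low$margin, 2), 0.26)
  expect_true(low$keeps_pace)
  intlow <- kp[kp$scenario == "Intermediate-Low" & kp$year == 2100, ]
  expect_true(intlow$keeps_pace)
  expect_false(kp$keeps_pace[kp$scenario == "High" & kp$year == 2100])

  none <- keep_pace(0, sc)
  expect_false(any(none$keeps_pace))

  # boundary inclusive: accretion exactly matching rise keeps pace
  exact <- keep_pace(0.36 / 84 * 1000, sc, target_years = 2100)
  expect_true(exact$keeps_pace[exact$scenario == "Low"])
  expect_error(keep_pace(1, sc, target_years = 2075), "2075")
})

test_that("scenario sets enforce monotone rise", {
  bad <- data.frame(scenario = c("Low", "Low"), year = c(2050, 2100),
                    rise = c(0.5, 0.3))
  expect_error(slr_scenarios(bad), "non-decreasing in time")
  bad2 <- data.frame(scenario = c("Low", "High"), year = 2100,
                     rise = c(2.0, 0.3))
  expect_error(slr_scenarios(bad2), "across ordered scenarios")
})

test_that("the historic-baseline offset follows the restored-budget
           chain", {
  ho <- historic_offset(rates = rates, bioerosion = 0)
  expect_equal(ho$historic_production, 0.62 * 29.07)
  f <- 1000 * 0.62 * 29.07 / 1450
  expect_equal(ho$historic_rap, f * 100 / 49)
  expect_equal(ho$offset, f * 100 / 49 - 13.4)

  # when the historic RAP equals the observed maximum the offset is 0
  zero <- historic_offset(rates = rates, bioerosion = 0,
                          observed_max_accretion = ho$historic_rap)
  expect_equal(zero$offset, 0)

  # the operative default constant: 3.08 mm y-1 off the accretion rate
  expect_equal(round(7.38 - 3.08, 2), 4.30)
  expect_equal(project_elevation(7.38, 2100) -
                 lower_bound_elevation(7.38),
               3.08 * 84 / 1000)
})
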