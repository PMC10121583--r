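rec <- function(time, mass_dry = 1000, buoyant = NULL, height = 10,
                d_max = 10, d_min = 10, status = "alive") {
  if (is.null(buoyant)) buoyant <- mass_dry * (1 - 1.023 / 2.93)
  data.frame(colony_id = "C1", species = "acropora_palmata",
             station = "south", time = time, buoyant_mass = buoyant,
             height = height, d_max = d_max, d_min = d_min,
             status = status)
}

test_that("elliptical footprint area", {
  expect_equal(ellipse_area(2, 2), pi)
  expect_equal(round(ellipse_area(10, 5), 2), 39.27)
  expect_equal(ellipse_area(4, 6 / 2), 4 * ellipse_area(2, 1.5))
  expect_error(ellipse_area(0, 0), "positive")
  expect_error(ellipse_area(2, 3), "d_max")
})

test_that("buoyant-weight conversion inverts Archimedes", {
  expect_equal(buoyant_to_dry(5, rho_seawater = 0), 5)
  m_b <- 100 * (1 - 1.023 / 2.93)  # 65.085 g
  expect_equal(buoyant_to_dry(m_b), 100)
  expect_equal(round(m_b, 1), 65.1)
  expect_equal(buoyant_to_dry(2 * m_b), 200)
  expect_error(buoyant_to_dry(1, rho_seawater = 3, rho_skeleton = 2.9),
               "rho_skeleton")
})

test_that("calcification rate normalizes mass gain by area and time", {
  r0 <- rec(0, mass_dry = 1000)
  expect_equal(calcification_rate(r0, rec(1, mass_dry = 1000))$rate, 0)

  # ~29.07 kg m-2 y-1: +1.4535 kg dry over 1 y at mean footprint 0.05 m2
  d0 <- sqrt(4 * 400 / pi)  # 400 cm2 start
  d1 <- sqrt(4 * 600 / pi)  # 600 cm2 end; mean 500 cm2 = 0.05 m2
  r0 <- rec(0, mass_dry = 1000, d_max = d0, d_min = d0)
  r1 <- rec(1, mass_dry = 2453.5, d_max = d1, d_min = d1)
  expect_equal(calcification_rate(r0, r1)$rate, 29.07)
  expect_equal(calcification_rate(r0, r1, area_mode = "start")$rate,
               1.4535 / 0.04)
  expect_equal(calcification_rate(r0, r1, area_mode = "end")$rate,
               1.4535 / 0.06)

  dead <- calcification_rate(r0, rec(1, mass_dry = 0.1,
                                     status = "dead"))
  expect_true(dead$dead_endpoint)
  expect_true(is.na(dead$rate))
  expect_error(calcification_rate(r1, r0), "ordered")
})

test_that("interval splitting leaves the rate unchanged for linear
           growth at constant area", {
  masses <- seq(1000, 1600, length.out = 5)
  times <- seq(0, 2, length.out = 5)
  recs <- lapply(seq_along(times),
                 function(i) rec(times[i], mass_dry = masses[i]))
  whole <- calcification_rate(recs[[1]], recs[[5]])$rate
  for (i in 2:5) {
    expect_equal(calcification_rate(recs[[i - 1]], recs[[i]])$rate,
                 whole)
  }
})

test_that("extension rates are finite differences", {
  r0 <- rec(0)
  expect_equal(unname(extension_rates(r0, rec(1))), c(0, 0))
  expect_equal(extension_rates(r0, rec(1, height = 17))[["height"]], 7.0)
  d0 <- sqrt(4 * 100 / pi)
  d1 <- sqrt(4 * 296.21 / pi)
  got <- extension_rates(rec(0, mass_dry = 1, d_max = d0, d_min = d0),
                         rec(1, mass_dry = 1, d_max = d1, d_min = d1))
  expect_equal(got[["area"]], 196.21)
  expect_error(extension_rates(r0, r0), "ordered")
})

test_that("zero-noise synthetic colonies recover the true rates
           exactly", {
  p <- synth_params(growth_noise_sd = c(mass = 0, height = 0,
                                        diameter = 0),
                    visit_survival = 1)
  gen <- gen_growth(p, n_colonies = 5, n_visits = 4, seed = 1)
  rates <- growth_rates(gen$records)
  expect_equal(rates$calcification, rep(29.07, 5), tolerance = 1e-9)
  expect_equal(rates$height_rate, rep(6.99, 5), tolerance = 1e-9)
  expect_equal(rates$area_rate, rep(196.21, 5), tolerance = 1e-9)
})

test_that("noisy colony summaries recover generator parameters within
           sampling error", {
  gen <- gen_growth(synth_params(), n_colonies = 30, n_visits = 5,
                    seed = 7)
  rates <- growth_rates(gen$records)
  summ <- summarise_growth(rates)
  expect_true(abs(summ$calcification_mean - 29.07) <=
                2 * max(summ$calcification_se, 0.5))
  expect_true(abs(summ$height_rate_mean - 6.99) <=
                2 * max(summ$height_rate_se, 0.5))
  # station-level averaging is exposed alongside colony-level
  by_station <- summarise_growth(rates, level = "station")
  expect_equal(by_station$n, 3)
})

test_that("dead colonies are excluded from rate summaries", {
  p <- synth_params(growth_noise_sd = c(mass = 0, height = 0,
                                        diameter = 0),
                    visit_survival = 0.5)
  gen <- gen_growth(p, n_colonies = 40, n_visits = 5, seed = 5)
  rates <- growth_rates(gen$records)
  dead_final <- tapply(gen$records$status, gen$records$colony_id,
                       function(s) utils::tail(s, 1) == "dead")
  expect_gt(sum(dead_final), 0)          # thinning actually occurred
  expect_false(any(rates$colony_id %in% names(dead_final)[dead_final]))
  expect_true(all(is.finite(rates$calcification)))
})

test_that("growth records round-trip through CSV with validation", {
  gen <- gen_growth(synth_params(), n_colonies = 3, n_visits = 3,
                    seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(gen$records, path, row.names = FALSE)
  back <- read_growth_records(path)
  expect_equal(nrow(back), nrow(gen$records))
  bad <- gen$records
  bad$status[1] <- "zombie"
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_growth_records(path), "status")
})
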