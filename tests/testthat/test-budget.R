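rates <- make_rates()

test_that("gross production multiplies cover, rate and rugosity", {
  expect_equal(round(gross_production(c(acropora_palmata = 1),
                                      rates)$total, 2), 36.24)
  expect_equal(gross_production(c(acropora_palmata = 0,
                                  pseudodiploria = 0), rates)$total, 0)
  # two taxa at 20%/30% with c x r of 5/10 -> 1.0 + 3.0
  rt <- rate_table(calcification = c(t1 = 5, t2 = 10),
                   rugosity = c(t1 = 1), density = c(t1 = 1500),
                   parrotfish = rates$parrotfish)
  g <- gross_production(c(t1 = 0.2, t2 = 0.3), rt)
  expect_equal(g$total, 4.0)
  expect_equal(sum(g$by_taxon), g$total)
  expect_error(gross_production(c(t1 = 1.2), rt), "\\[0, 1\\]")
})

test_that("parrotfish bioerosion averages the two belt transects", {
  expect_equal(parrotfish_bioerosion(empty_fish(), rates), 0)
  one_fish <- data.frame(
    transect = c(1, 2), species = "sparisoma_viride",
    size_bin = 150, phase = c("terminal", "terminal"), count = c(1, 0)
  )
  # 120,000 g over one 120-m2 belt -> 1 kg m-2 y-1; mean with 0 -> 0.5
  expect_equal(parrotfish_bioerosion(one_fish, rates, belt_area = 120),
               0.5)
  swapped <- one_fish
  swapped$transect <- c(2, 1)
  expect_equal(parrotfish_bioerosion(swapped, rates),
               parrotfish_bioerosion(one_fish, rates))
  missing <- one_fish
  missing$size_bin <- 300
  expect_error(parrotfish_bioerosion(missing, rates), "sparisoma_viride")
  single <- one_fish[1, ]
  expect_error(parrotfish_bioerosion(single, rates), "one fish transect")
  expect_warning(
    expect_equal(parrotfish_bioerosion(single, rates, lenient = TRUE), 1),
    "one fish transect"
  )
})

test_that("urchin bioerosion applies allometry and reingestion", {
  expect_equal(urchin_bioerosion(empty_urchins(), rates), 0)
  ten <- data.frame(species = "echinometra_lucunter", size_bin = 40,
                    count = 10)
  # 1 ind m-2 x 0.2 kg ind-1 y-1 x 0.57
  expect_equal(urchin_bioerosion(ten, rates, transect_area = 10), 0.114)
  doubled <- ten
  doubled$count <- 20
  expect_equal(urchin_bioerosion(doubled, rates),
               2 * urchin_bioerosion(ten, rates))
})

test_that("endolithic bioerosion scales with available substratum", {
  expect_equal(substrate_bioerosion(1.0, rates = rates)[["macro"]], 0.4)
  expect_equal(unname(substrate_bioerosion(0, rates = rates)), c(0, 0))
  expect_equal(unname(substrate_bioerosion(0.5, 0.5, rates)),
               c(0.20, 0.135))
  expect_error(substrate_bioerosion(1.2, rates = rates), "\\[0, 1\\]")
})

test_that("framework density is the cover-weighted mean", {
  expect_equal(framework_density(c(acropora_palmata = 0.2), rates), 1450)
  rt <- rate_table(calcification = c(a = 1, b = 1),
                   rugosity = c(a = 1), density = c(a = 1500, b = 1800),
                   parrotfish = rates$parrotfish)
  expect_equal(framework_density(c(a = 0.25, b = 0.25), rt), 1650)
  rt2 <- rate_table(calcification = c(a = 1, b = 1),
                    rugosity = c(a = 1), density = c(a = 1000, b = 2000),
                    parrotfish = rates$parrotfish)
  expect_equal(framework_density(c(a = 0.1, b = 0.3), rt2), 1750)
  expect_error(framework_density(c(sand = 1), rates), "zero coral")
})

test_that("accretion potential credits sediment and void fill only when
           the budget is positive", {
  expect_equal(unname(accretion_potential(0, 1670, rates)), c(0, 0))
  # F = 1 mm y-1 -> A = 100/49
  acc <- accretion_potential(1.670, 1670, rates)
  expect_equal(acc[["framework"]], 1)
  expect_equal(acc[["accretion"]], 100 / 49)
  acc <- accretion_potential(-1.670, 1670, rates)
  expect_equal(unname(acc), c(-1, -1))
  expect_error(accretion_potential(1, 0, rates), "positive")
})

test_that("elevation projection is accretion times elapsed time", {
  expect_equal(round(project_elevation(7.38, 2100), 2), 0.62)
  expect_equal(round(project_elevation(7.38, 2050), 2), 0.25)
  expect_equal(project_elevation(0, 2100), 0)
  expect_error(project_elevation(1, 2010), ">= base_year")
})

test_that("site_budget matches an independent hand computation", {
  fish <- data.frame(
    transect = c(1, 2), species = "sparisoma_viride",
    size_bin = 150, phase = "initial", count = c(2, 0)
  )
  urchins <- data.frame(species = "echinometra_lucunter",
                        size_bin = 40, count = 10)
  cs <- make_site(c(acropora_palmata = 1, pseudodiploria = 2,
                    dead_coral = 4, sand = 3),
                  fish = fish, urchins = urchins)
  b <- site_budget(cs, rates)

  # independent recomputation from the raw tallies
  g <- 0.1 * 10.88 * 3.3309 + 0.2 * 9.84 * 1.79
  p <- ((2 * 60000 / 120 / 1000) + 0) / 2
  u <- (10 / 10) * (0.0016 * 50^3 / 1000) * 0.57
  ma <- 0.4 * 0.4
  mi <- 0.4 * 0.27
  net <- g - (p + u + ma + mi)
  d <- (0.1 * 1450 + 0.2 * 1600) / 0.3
  f <- 1000 * net / d
  a <- f * 100 / 49

  expect_equal(b$gross, g)
  expect_equal(b$parrotfish, p)
  expect_equal(b$urchin, u)
  expect_equal(b$macro, ma)
  expect_equal(b$micro, mi)
  expect_equal(b$net, net, tolerance = 1e-12)
  expect_equal(b$density, d)
  expect_equal(b$framework, f)
  expect_equal(b$accretion, a)
  expect_equal(b$elev_2100, a * 84 / 1000)

  # determinism: identical censuses give identical budgets
  expect_identical(site_budget(cs, rates), b)
})

test_that("an all-abiotic site erodes through endoliths only", {
  cs <- make_site(c(dead_coral = 10))
  b <- site_budget(cs, rates)
  expect_equal(b$gross, 0)
  expect_equal(b$parrotfish + b$urchin, 0)
  expect_equal(b$net, -(0.4 + 0.27))
  expect_lt(b$accretion, 0)
  expect_equal(b$density, 1670)
  expect_equal(b$accretion, b$framework)
})

test_that("budget identity and the positive-branch multiplier hold over
           synthetic surveys", {
  gen <- gen_census(synth_params(), n_per_zone = 2, seed = 99)
  budgets <- site_budgets(gen$censuses, default_rate_table())
  expect_equal(budgets$net,
               budgets$gross - (budgets$parrotfish + budgets$urchin +
                                  budgets$macro + budgets$micro),
               tolerance = 1e-12)
  pos <- budgets$net > 0
  expect_equal(budgets$accretion[pos] / budgets$framework[pos],
               rep(100 / 49, sum(pos)))
  expect_equal(budgets$accretion[!pos], budgets$framework[!pos])
  expect_equal(sign(budgets$accretion), sign(budgets$net))
})

test_that("raising coral cover never lowers accretion potential", {
  base <- make_site(c(acropora_palmata = 1, dead_coral = 4, sand = 5))
  more <- make_site(c(acropora_palmata = 3, dead_coral = 4, sand = 3))
  expect_gte(site_budget(more, rates)$accretion,
             site_budget(base, rates)$accretion)
})

test_that("zonal aggregation reports means and standard errors", {
  budgets <- data.frame(
    site_id = c("a", "b", "c"), sector = "northern",
    habitat = "fore_reef",
    gross = c(1, 2, 3), parrotfish = 0, urchin = 0, macro = 0,
    micro = 0, net = c(1, 2, 3), density = 1670,
    framework = c(1, 2, 3), accretion = c(1, 2, 3),
    elev_2050 = 0, elev_2100 = 0
  )
  z <- aggregate_zones(budgets, overall = FALSE)
  expect_equal(z$n_sites, 3)
  expect_equal(z$accretion_mean, 2)
  expect_equal(z$accretion_se, sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(round(z$accretion_se, 3), 0.577)

  one <- aggregate_zones(budgets[1, ], overall = FALSE)
  expect_false(one$se_defined)
  expect_equal(one$accretion_se, 0)
  expect_error(aggregate_zones(budgets[0, ]), "no budgets")
})

test_that("zonal aggregation recovers generating zone means at survey
           scale", {
  params <- synth_params(zone_cover = list(
    "southern.reef_crest" = c(acropora_palmata = 0.10,
                              pseudodiploria = 0.05, orbicella = 0.02,
                              millepora = 0.01, porites_astreoides = 0.01,
                              cca = 0.05, dead_coral = 0.31, sand = 0.25,
                              macroalgae = 0.15, other = 0.05)
  ))
  gen <- gen_census(params, n_per_zone = 9, seed = 21)
  budgets <- site_budgets(gen$censuses, default_rate_table())
  z <- aggregate_zones(budgets, overall = TRUE)
  expect_equal(nrow(z), 7)
  # the enriched southern reef crest out-produces every other zone
  sz <- z[z$sector == "southern" & z$habitat == "reef_crest", ]
  others <- z[!(z$sector %in% c("southern", "all")) |
                (z$sector == "southern" & z$habitat != "reef_crest"), ]
  others <- others[others$sector != "all", ]
  expect_true(all(sz$gross_mean > others$gross_mean))
})
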