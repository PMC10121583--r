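#' An outplanting scenario for the reef-crest cohort model
#'
#' The model follows a single cohort of A. palmata outplants established
#' at the end of a 2020-2030 restoration window. Colonies grow
#' isometrically in planar area at a fixed rate (the measured species mean
#' 196.21 cm2 y-1 by default), survive each decade with probability s_k,
#' and do not reproduce sexually; asexual fragmentation is folded into the
#' decadal survival (3% colony survival combined with 55% net
#' fragmentation gives 58%, rounded to 60%). Mortality regimes: `fixed`
#' keeps s_k = s0; `increasing` impacts multiply survival by 0.95 each
#' subsequent decade; `decreasing` impacts multiply it by 1.05 (clamped
#' to 1).
#'
#' @param n_outplants cohort size (presets 100,000 / 250,000 / 500,000).
#' @param reef_area m2 of reef-crest habitat (default 166,407).
#' @param growth_rate planar-area growth g, cm2 y-1 (default 196.21).
#' @param base_survival per-decade survival s0 (default 0.60).
#' @param mortality_mode `"fixed"`, `"increasing"` or `"decreasing"`.
#' @param multiplier per-decade survival multiplier for the non-fixed
#'   modes (0.95 increasing impacts, 1.05 decreasing impacts; ignored for
#'   `fixed`).
#' @param establishment_year cohort start (default 2030).
#' @param horizon last projected year (default 2100).
#' @return Object of class `population_scenario`.
#' @export
population_scenario <- function(n_outplants,
                                reef_area = 166407,
                                growth_rate = 196.21,
                                base_survival = 0.60,
                                mortality_mode = c("fixed", "increasing",
                                                   "decreasing"),
                                multiplier = NULL,
                                establishment_year = 2030,
                                horizon = 2100) {
  mortality_mode <- match.arg(mortality_mode)
  if (n_outplants < 0) stop("n_outplants must be >= 0")
  if (base_survival <= 0 || base_survival > 1) {
    stop("base_survival must lie in (0, 1]")
  }
  if (horizon <= establishment_year) {
    stop("horizon must be after the establishment year")
  }
  multiplier <- multiplier %||%
    switch(mortality_mode, fixed = 1, increasing = 0.95,
           decreasing = 1.05)
  structure(
    list(n_outplants = n_outplants, reef_area = reef_area,
         growth_rate = growth_rate, base_survival = base_survival,
         mortality_mode = mortality_mode, multiplier = multiplier,
         establishment_year = establishment_year, horizon = horizon),
    class = "population_scenario"
  )
}

#' Per-decade survival schedule
#'
#' s_k = s0 * m^(k-1), clamped to at most 1, where k = 1 is the first
#' post-establishment decade (2030-2040 under the defaults) and m is 1,
#' 0.95 or 1.05 for fixed, increasing-impact and decreasing-impact
#' mortality. Under the defaults the seventh decade reaches 0.441 (44%)
#' and 0.804 (80%) in the increasing and decreasing modes.
#'
#' @param mode `"fixed"`, `"increasing"` or `"decreasing"`.
#' @param s0 base per-decade survival (default 0.60).
#' @param multiplier override for m (defaults by mode).
#' @param decades number of decades (default 7: 2030 to 2100).
#' @return Numeric vector of per-decade survival probabilities.
#' @export
survival_schedule <- function(mode = c("fixed", "increasing",
                                       "decreasing"),
                              s0 = 0.60, multiplier = NULL, decades = 7) {
  mode <- match.arg(mode)
  if (decades < 1) stop("decades must be >= 1")
  m <- multiplier %||% switch(mode, fixed = 1, increasing = 0.95,
                              decreasing = 1.05)
  pmin(s0 * m^(seq_len(decades) - 1), 1)
}

#' Decadal net survival composed from colony survival and fragmentation
#'
#' The decadal survival parameter combines direct colony survival with
#' the net contribution of asexual fragmentation: s = survival +
#' fragmentation. The defaults (0.03 + 0.55 = 0.58) round to the model's
#' 0.60.
#'
#' @param colony_survival decadal colony survival fraction (default 0.03).
#' @param net_fragmentation decadal net fragmentation fraction
#'   (default 0.55).
#' @return List: `net` (exact sum) and `rounded` (to one decimal).
#' @export
compose_decadal_survival <- function(colony_survival = 0.03,
                                     net_fragmentation = 0.55) {
  net <- colony_survival + net_fragmentation
  list(net = net, rounded = round(net, 1))
}

#' Deterministic cohort cover trajectory
#'
#' At every decade-end year y from establishment+10 to the horizon:
#' mean colony planar area = g * (y - establishment) cm2 (the initial
#' branch-tip footprint is excluded), surviving fraction = product of the
#' per-decade survivals elapsed, and added cover = N * fraction * area /
#' reef_area. Cover is linear in N by construction.
#'
#' @param scenario a `population_scenario`.
#' @return data.frame: year, decade, survival (that decade's s_k),
#'   surviving_fraction, colony_area_m2, added_cover (fraction of reef
#'   area).
#' @export
project_cover <- function(scenario) {
  years <- seq(scenario$establishment_year + 10, scenario$horizon, by = 10)
  decades <- seq_along(years)
  s <- survival_schedule(scenario$mortality_mode,
                         s0 = scenario$base_survival,
                         multiplier = scenario$multiplier,
                         decades = length(decades))
  frac <- cumprod(s)
  area_m2 <- scenario$growth_rate *
    (years - scenario$establishment_year) / 1e4
  data.frame(
    year = years, decade = decades, survival = s,
    surviving_fraction = frac, colony_area_m2 = area_m2,
    added_cover = scenario$n_outplants * frac * area_m2 /
      scenario$reef_area
  )
}

#' Monte-Carlo per-colony validator of the cohort model
#'
#' Simulates stochastic decadal survival of every colony (i.i.d.
#' Bernoulli thinning, drawn as one binomial count per decade) and
#' averages the resulting cover trajectories over replicates. The
#' replicate mean converges on [project_cover()].
#'
#' @param scenario a `population_scenario`.
#' @param n_replicates number of replicate cohorts.
#' @param seed RNG seed (required for reproducibility).
#' @return data.frame: year, mean_cover, sd_cover across replicates.
#' @export
mc_population_oracle <- function(scenario, n_replicates, seed) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  set.seed(seed)
  det <- project_cover(scenario)
  reps <- vapply(seq_len(n_replicates), function(r) {
    alive <- scenario$n_outplants
    vapply(seq_len(nrow(det)), function(k) {
      alive <<- stats::rbinom(1, alive, det$survival[k])
      alive * det$colony_area_m2[k] / scenario$reef_area
    }, numeric(1))
  }, numeric(nrow(det)))
  reps <- matrix(reps, nrow = nrow(det))
  data.frame(
    year = det$year,
    mean_cover = apply(reps, 1, mean),
    sd_cover = apply(reps, 1, stats::sd)
  )
}

#' Carbonate budget under an A. palmata restoration scenario
#'
#' Adds `delta_cover` of A. palmata to a site's budget: gross production
#' gains delta_cover x restored_rate, using the locally measured,
#' planar-normalized calcification rate (29.07 kg m-2 y-1 by default,
#' deliberately *without* the rugosity correction that the census rate
#' 36.24 carries — the measured rate is the more conservative choice).
#' Framework density is recomputed from the updated coral covers, the
#' accretion potential re-derived, and elevation projections refreshed.
#' Substrate bioerosion is unchanged by default; `deduct_substrate`
#' removes the newly occupied fraction from the dead-coral substratum and
#' rescales macro/micro bioerosion accordingly.
#'
#' @param budget one-row `budget_result` from [site_budget()] (its
#'   `cover` attribute supplies the site covers), or a list
#'   `list(budget = <row>, cover = <named fractions>)`.
#' @param delta_cover added A. palmata cover fraction in (0, 0.30].
#' @param rates a `rate_table`.
#' @param restored_rate kg m-2 y-1 per unit added cover (default 29.07).
#' @param deduct_substrate see above.
#' @param taxon name of the restored taxon (default
#'   `"acropora_palmata"`).
#' @return One-row data.frame like [site_budget()]'s, with attribute
#'   `cover` updated.
#' @export
restored_budget <- function(budget, delta_cover, rates,
                            restored_rate = 29.07,
                            deduct_substrate = FALSE,
                            taxon = "acropora_palmata") {
  if (is.list(budget) && !is.data.frame(budget)) {
    cover <- budget$cover
    budget <- budget$budget
  } else {
    cover <- attr(budget, "cover")
  }
  if (is.null(cover)) stop("restored_budget needs the site cover vector")
  if (delta_cover < 0 || delta_cover > 0.30) {
    stop("delta_cover must lie in [0, 0.30]")
  }
  live <- sum(cover[intersect(names(cover), names(rates$calcification))])
  if (live + delta_cover > 1) {
    stop("added cover would push total cover past 100%")
  }
  new_cover <- cover
  if (!taxon %in% names(new_cover)) new_cover[taxon] <- 0
  new_cover[taxon] <- new_cover[taxon] + delta_cover

  gross <- budget$gross + delta_cover * restored_rate
  macro <- budget$macro
  micro <- budget$micro
  if (deduct_substrate) {
    dead <- sum(cover[intersect(names(cover),
                                rates$substrate_categories)])
    avail <- sum(cover[intersect(names(cover),
                                 rates$micro_substrate_categories)])
    new_dead <- max(dead - delta_cover, 0)
    new_avail <- max(avail - delta_cover, 0)
    sub <- substrate_bioerosion(new_dead, new_avail, rates)
    macro <- unname(sub[["macro"]])
    micro <- unname(sub[["micro"]])
    new_cover <- adjust_substrate_cover(new_cover, rates, dead, new_dead)
  }
  net <- gross - (budget$parrotfish + budget$urchin + macro + micro)
  density <- if (net > 0) framework_density(new_cover, rates) else
    rates$default_density
  acc <- accretion_potential(net, density, rates)
  out <- budget
  out$gross <- gross
  out$macro <- macro
  out$micro <- micro
  out$net <- net
  out$density <- density
  out$framework <- unname(acc[["framework"]])
  out$accretion <- unname(acc[["accretion"]])
  out$elev_2050 <- project_elevation(out$accretion, 2050)
  out$elev_2100 <- project_elevation(out$accretion, 2100)
  attr(out, "cover") <- new_cover
  out
}

# Scale the recorded substrate-category covers down to a new dead-coral
# total (keeps the cover vector consistent when restoration overgrows
# dead substratum).
adjust_substrate_cover <- function(cover, rates, old_dead, new_dead) {
  cats <- intersect(names(cover), rates$substrate_categories)
  if (length(cats) == 0 || old_dead <= 0) return(cover)
  cover[cats] <- cover[cats] * new_dead / old_dead
  cover
}

#' Sea-level-rise scenario set
#'
#' Cumulative rise (m, relative to the 2016 survey datum) at 2050 and
#' 2100 for the five named scenarios, plus the sea-level offsets at which
#' the hydrodynamic total-water-level tables were computed. The bundled
#' 2100 values anchor on the projections for St. Croix (Low ~0.36 m,
#' Intermediate-Low ~0.5 m, Intermediate ~1.0 m, High ~2.0 m); all
#' entries are replaceable configuration.
#'
#' @param rise data.frame with columns `scenario`, `year`, `rise`;
#'   `NULL` for the bundled default.
#' @param offsets TWL table sea-level offsets (m).
#' @return Object of class `slr_scenarios`.
#' @export
slr_scenarios <- function(rise = NULL,
                          offsets = c(0.0, 0.2, 0.5, 1.2, 2.0)) {
  levels_ <- c("Low", "Intermediate-Low", "Intermediate",
               "Intermediate-High", "High")
  if (is.null(rise)) {
    rise <- data.frame(
      scenario = rep(levels_, times = 2),
      year = rep(c(2050, 2100), each = 5),
      rise = c(0.15, 0.20, 0.28, 0.35, 0.43,
               0.36, 0.52, 1.00, 1.50, 2.00)
    )
  }
  rise$scenario <- factor(rise$scenario, levels = levels_)
  if (anyNA(rise$scenario)) stop("unknown scenario name")
  for (sc in split(rise, rise$scenario)) {
    if (is.unsorted(sc$rise[order(sc$year)])) {
      stop("rise must be non-decreasing in time within scenario ",
           sc$scenario[1])
    }
  }
  for (yr in split(rise, rise$year)) {
    if (is.unsorted(yr$rise[order(yr$scenario)])) {
      stop("rise must be non-decreasing across ordered scenarios at year ",
           yr$year[1])
    }
  }
  structure(list(rise = rise, offsets = offsets),
            class = "slr_scenarios")
}

#' Can a reef keep pace with sea-level rise?
#'
#' For each scenario and target year, the cumulative accretion
#' A x (year - base_year)/1000 is compared with the scenario's cumulative
#' rise; the margin (m) is accretion minus rise and the reef keeps pace
#' iff the margin is >= 0 (boundary inclusive).
#'
#' @param accretion reef-accretion potential, mm y-1.
#' @param scenarios an `slr_scenarios`.
#' @param target_years years to assess (default 2050 and 2100).
#' @param base_year datum year (default 2016).
#' @return data.frame: scenario, year, rise, accreted, margin, keeps_pace.
#' @export
keep_pace <- function(accretion, scenarios,
                      target_years = c(2050, 2100), base_year = 2016) {
  rise <- scenarios$rise[scenarios$rise$year %in% target_years, ]
  missing <- setdiff(target_years, rise$year)
  if (length(missing) > 0) {
    stop("scenario set lacks rise values for year(s): ",
         paste(missing, collapse = ", "))
  }
  accreted <- project_elevation(accretion, rise$year, base_year)
  data.frame(
    scenario = as.character(rise$scenario), year = rise$year,
    rise = rise$rise, accreted = accreted,
    margin = accreted - rise$rise,
    keeps_pace = accreted - rise$rise >= 0
  )
}

#' Historic-baseline lower uncertainty on reef-accretion potential
#'
#' Carbonate budgets ignore physical erosion and chemical dissolution, so
#' the accretion potential they yield is a maximum. A lower uncertainty
#' bound is derived by reconstructing the historic reef-accretion
#' potential at the maximum historically observed A. palmata cover
#' (62% in the 1970s) through the restored-budget chain, and subtracting
#' the maximum accretion actually recorded in Holocene cores
#' (13.4 mm y-1). The operative default offset is 3.08 mm y-1.
#'
#' @param historic_cover historic A. palmata cover fraction
#'   (default 0.62).
#' @param rates a `rate_table`.
#' @param bioerosion total present-day bioerosion to charge against the
#'   historic production, kg m-2 y-1 (positive magnitude).
#' @param observed_max_accretion Holocene maximum, mm y-1 (default 13.4).
#' @param production_rate kg m-2 y-1 per unit cover (default 29.07).
#' @return List: `historic_production` (kg m-2 y-1, gross),
#'   `historic_rap` (mm y-1) and `offset` (mm y-1, historic RAP minus the
#'   observed maximum).
#' @export
historic_offset <- function(historic_cover = 0.62, rates,
                            bioerosion = 0,
                            observed_max_accretion = 13.4,
                            production_rate = 29.07) {
  if (historic_cover <= 0 || historic_cover > 1) {
    stop("historic_cover must lie in (0, 1]")
  }
  if (observed_max_accretion <= 0) {
    stop("observed_max_accretion must be positive")
  }
  production <- historic_cover * production_rate
  net <- production - bioerosion
  density <- rates$density[["acropora_palmata"]] %||%
    rates$default_density
  rap <- accretion_potential(net, density, rates)[["accretion"]]
  list(historic_production = production, historic_rap = unname(rap),
       offset = unname(rap) - observed_max_accretion)
}

#' Lower-bound elevation projection under the historic offset
#'
#' @param accretion mm y-1.
#' @param offset mm y-1 subtracted from the accretion potential
#'   (default 3.08, the historic-baseline estimate).
#' @param target_year,base_year projection window.
#' @return Elevation change in m using (accretion - offset).
#' @export
lower_bound_elevation <- function(accretion, offset = 3.08,
                                  target_year = 2100, base_year = 2016) {
  project_elevation(accretion - offset, target_year, base_year)
}
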