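#' Gross carbonate production from percent cover
#'
#' G = sum over calcifying taxa of cover_t x c_t x r_t, where c_t is the
#' taxon calcification rate at 100% planar cover (kg CaCO3 m-2 y-1) and
#' r_t the rugosity correction that converts planar cover to
#' three-dimensional calcifying surface (1 for coralline algae). Taxa in
#' `cover` that the rate table does not list as calcifiers contribute
#' nothing; a calcifier with positive cover but no rate is an error.
#'
#' @param cover named numeric cover fractions in \[0, 1\].
#' @param rates a `rate_table`.
#' @return List with `total` (kg CaCO3 m-2 y-1) and `by_taxon`, a named
#'   vector over calcifying taxa that sums to `total`.
#' @export
gross_production <- function(cover, rates) {
  if (any(cover < 0 | cover > 1)) {
    stop("cover fractions must lie in [0, 1]")
  }
  calcifiers <- names(rates$calcification)
  by_taxon <- vapply(calcifiers, function(t) {
    x <- if (t %in% names(cover)) cover[[t]] else 0
    r <- if (t %in% names(rates$rugosity)) rates$rugosity[[t]] else 1
    x * rates$calcification[[t]] * r
  }, numeric(1))
  list(total = sum(by_taxon), by_taxon = by_taxon)
}

#' Parrotfish bioerosion at a site
#'
#' Per belt transect, every observed (species, size bin, life phase) count
#' is multiplied by its per-individual rate (g ind-1 y-1), summed, and
#' converted to kg m-2 y-1 over the belt area; the site value is the mean
#' of the two transects.
#'
#' @param fish_counts data.frame (`transect`, `species`, `size_bin`,
#'   `phase`, `count`).
#' @param rates a `rate_table`.
#' @param belt_area m2 per transect (default 120).
#' @param lenient if `TRUE`, a single-transect site is used as-is with a
#'   warning instead of an error.
#' @return kg CaCO3 m-2 y-1 (positive magnitude).
#' @export
parrotfish_bioerosion <- function(fish_counts, rates, belt_area = 120,
                                  lenient = FALSE) {
  fish_counts <- as.data.frame(fish_counts)
  transects <- sort(unique(fish_counts$transect))
  if (length(transects) == 0) return(0)
  if (length(transects) < 2) {
    msg <- "only one fish transect present"
    if (!lenient) stop(msg, " (use lenient = TRUE to accept)")
    warning(msg, "; using it as the site value")
  }
  merged <- merge(fish_counts, rates$parrotfish,
                  by = c("species", "size_bin", "phase"), all.x = TRUE)
  if (anyNA(merged$rate)) {
    bad <- merged[is.na(merged$rate), ]
    stop("no parrotfish rate for: ",
         paste(unique(paste(bad$species, bad$size_bin, bad$phase)),
               collapse = "; "))
  }
  per_transect <- vapply(transects, function(tr) {
    rows <- merged$transect == tr
    sum(merged$count[rows] * merged$rate[rows]) / belt_area / 1000
  }, numeric(1))
  mean(per_transect)
}

#' Urchin bioerosion at a site
#'
#' Urchin densities (ind m-2, from counts over the benthic transect area)
#' are multiplied by the size-specific rate from the configured test-size
#' allometry evaluated at bin midpoints, scaled by the sediment
#' reingestion factor (default 0.57), and summed over species and bins.
#'
#' @param urchin_counts data.frame (`species`, `size_bin`, `count`);
#'   `size_bin` is the 20-mm bin lower edge (mm).
#' @param rates a `rate_table`.
#' @param transect_area m2 (default 10).
#' @param bin_width mm (default 20).
#' @return kg CaCO3 m-2 y-1 (positive magnitude).
#' @export
urchin_bioerosion <- function(urchin_counts, rates, transect_area = 10,
                              bin_width = 20) {
  urchin_counts <- as.data.frame(urchin_counts)
  if (nrow(urchin_counts) == 0 || sum(urchin_counts$count) == 0) return(0)
  mid <- urchin_counts$size_bin + bin_width / 2
  rate_kg <- urchin_rate(mid, rates) / 1000
  density <- urchin_counts$count / transect_area
  sum(density * rate_kg * rates$reingestion)
}

#' Endolithic macro- and microbioerosion
#'
#' Macroborers (clionid sponges, molluscs, polychaetes) erode the dead
#' coral substratum at `macro_rate`; microborers (bacteria, algae, fungi)
#' erode the available substrate at `micro_rate`. By default the same
#' dead-coral fraction feeds both; pass a distinct `available_substrate`
#' where the two substrata are scored separately.
#'
#' @param dead_coral_cover fraction in \[0, 1\].
#' @param available_substrate fraction in \[0, 1\]; defaults to
#'   `dead_coral_cover`.
#' @param rates a `rate_table`.
#' @return Named vector `c(macro = , micro = )` in kg CaCO3 m-2 y-1.
#' @export
substrate_bioerosion <- function(dead_coral_cover,
                                 available_substrate = dead_coral_cover,
                                 rates) {
  fr <- c(dead_coral_cover, available_substrate)
  if (any(fr < 0 | fr > 1)) stop("substrate fractions must lie in [0, 1]")
  c(macro = dead_coral_cover * rates$macro_rate,
    micro = available_substrate * rates$micro_rate)
}

#' Cover-weighted mean density of coral framework
#'
#' D_i = sum_n (x_n / X_i) d_n over live coral taxa, where x_n is the
#' cover of taxon n, X_i the total live coral cover, and d_n the taxon
#' skeletal density. Net-erosional sites use the regional average density
#' instead (handled by [site_budget()]); calling this with zero coral
#' cover is an error.
#'
#' @param cover named cover fractions (only taxa present in the rate
#'   table's density map count as coral).
#' @param rates a `rate_table`.
#' @return kg m-3.
#' @export
framework_density <- function(cover, rates) {
  coral <- intersect(names(cover), names(rates$density))
  x <- cover[coral]
  total <- sum(x)
  if (total <= 0) stop("framework density undefined with zero coral cover")
  sum((x / total) * rates$density[coral])
}

#' Framework accretion and reef-accretion potential
#'
#' F_i = 1000 x net / D_i converts the mass budget (kg CaCO3 m-2 y-1) to
#' vertical framework accretion (mm y-1) through framework density
#' (kg m-3). For net-positive sites the accretion potential additionally
#' credits sediment and void fill observed in Holocene reef cores:
#' A_i = F_i (1 + sed/frame + void/frame). Net-erosional sites get no such
#' credit: A_i = F_i.
#'
#' @param net_production kg CaCO3 m-2 y-1 (signed).
#' @param density framework density D_i, kg m-3.
#' @param rates a `rate_table` (source of sed/void/frame percentages).
#' @return Named vector `c(framework = F_i, accretion = A_i)` in mm y-1.
#' @export
accretion_potential <- function(net_production, density, rates) {
  if (density <= 0) stop("framework density must be positive")
  f <- 1000 * net_production / density
  a <- if (net_production > 0) {
    f * (1 + rates$sed_pct / rates$frame_pct +
           rates$void_pct / rates$frame_pct)
  } else {
    f
  }
  c(framework = f, accretion = a)
}

#' Project reef-elevation change from accretion potential
#'
#' @param accretion mm y-1.
#' @param target_year projection year.
#' @param base_year survey year (default 2016).
#' @return Elevation change in m (accretion x elapsed years / 1000).
#' @export
project_elevation <- function(accretion, target_year, base_year = 2016) {
  if (any(target_year < base_year)) {
    stop("target_year must be >= base_year")
  }
  accretion * (target_year - base_year) / 1000
}

#' Full carbonate budget for one census site
#'
#' Chains the component operations: percent cover from point counts, gross
#' production, the four bioerosion terms, net production (gross minus
#' total bioerosion), framework density (cover-weighted for net-positive
#' sites, the regional default 1670 kg m-3 for net-erosional ones),
#' framework accretion and reef-accretion potential, and projected
#' elevation change by 2050 and 2100.
#'
#' @param census a `site_census`.
#' @param rates a `rate_table`.
#' @param lenient passed to [parrotfish_bioerosion()].
#' @return One-row data.frame (class also `budget_result`) with columns
#'   site_id, sector, habitat, gross, parrotfish, urchin, macro, micro,
#'   net, density, framework, accretion, elev_2050, elev_2100, plus
#'   attribute `cover` (the site cover vector).
#' @export
site_budget <- function(census, rates, lenient = FALSE) {
  cover <- cover_from_points(census)
  g <- gross_production(cover, rates)
  p <- parrotfish_bioerosion(census$fish_counts, rates,
                             belt_area = census$fish_belt_area,
                             lenient = lenient)
  u <- urchin_bioerosion(census$urchin_counts, rates,
                         transect_area = census$benthic_transect_area)
  dead <- sum(cover[intersect(names(cover), rates$substrate_categories)])
  avail <- sum(cover[intersect(names(cover),
                               rates$micro_substrate_categories)])
  sub <- substrate_bioerosion(dead, avail, rates)
  net <- g$total - (p + u + sub[["macro"]] + sub[["micro"]])
  coral_cover <- sum(cover[intersect(names(cover), names(rates$density))])
  density <- if (net > 0) {
    if (coral_cover <= 0) {
      stop("site ", census$site_id,
           ": positive net production with zero coral cover")
    }
    framework_density(cover, rates)
  } else {
    rates$default_density
  }
  acc <- accretion_potential(net, density, rates)
  out <- data.frame(
    site_id = census$site_id, sector = census$sector,
    habitat = census$habitat,
    gross = g$total, parrotfish = p, urchin = u,
    macro = unname(sub[["macro"]]), micro = unname(sub[["micro"]]),
    net = net, density = density,
    framework = unname(acc[["framework"]]),
    accretion = unname(acc[["accretion"]]),
    elev_2050 = project_elevation(unname(acc[["accretion"]]), 2050),
    elev_2100 = project_elevation(unname(acc[["accretion"]]), 2100),
    stringsAsFactors = FALSE
  )
  attr(out, "cover") <- cover
  class(out) <- c("budget_result", class(out))
  out
}

#' Budgets for a collection of sites
#'
#' @param censuses list of `site_census`.
#' @inheritParams site_budget
#' @return data.frame with one row per site (cover attributes dropped).
#' @export
site_budgets <- function(censuses, rates, lenient = FALSE) {
  rows <- lapply(censuses, site_budget, rates = rates, lenient = lenient)
  out <- do.call(rbind, lapply(rows, function(r) {
    attr(r, "cover") <- NULL
    class(r) <- "data.frame"
    r
  }))
  rownames(out) <- NULL
  out
}

#' Zonal means and standard errors of carbonate budgets
#'
#' Groups per-site budgets by (sector, habitat) — and, with
#' `overall = TRUE`, adds an all-sites row — reporting the mean and
#' standard error (sample SD / sqrt(n)) of every budget quantity. A
#' single-site group reports SE 0 with `se_defined = FALSE`.
#'
#' @param budgets data.frame from [site_budgets()].
#' @param overall append an overall row (sector and habitat `"all"`).
#' @return data.frame with columns sector, habitat, n_sites, se_defined,
#'   and `<field>_mean` / `<field>_se` for each budget field.
#' @export
aggregate_zones <- function(budgets, overall = TRUE) {
  if (nrow(budgets) == 0) stop("no budgets to aggregate")
  fields <- c("gross", "parrotfish", "urchin", "macro", "micro", "net",
              "density", "framework", "accretion", "elev_2050",
              "elev_2100")
  summarise_group <- function(df, sector, habitat) {
    n <- nrow(df)
    row <- data.frame(sector = sector, habitat = habitat, n_sites = n,
                      se_defined = n > 1)
    for (f in fields) {
      row[[paste0(f, "_mean")]] <- mean(df[[f]])
      row[[paste0(f, "_se")]] <-
        if (n > 1) stats::sd(df[[f]]) / sqrt(n) else 0
    }
    row
  }
  groups <- unique(budgets[, c("sector", "habitat")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    df <- budgets[budgets$sector == g$sector &
                    budgets$habitat == g$habitat, ]
    summarise_group(df, g$sector, g$habitat)
  }))
  if (overall) out <- rbind(out, summarise_group(budgets, "all", "all"))
  rownames(out) <- NULL
  out
}

#' Mean cover by taxon within zones
#'
#' @param censuses list of `site_census`.
#' @return data.frame sector, habitat, category, mean_cover (fraction).
#' @export
zone_mean_cover <- function(censuses) {
  rows <- do.call(rbind, lapply(censuses, function(cs) {
    cov <- cover_from_points(cs)
    data.frame(sector = cs$sector, habitat = cs$habitat,
               category = names(cov), cover = as.numeric(cov))
  }))
  out <- dplyr::summarise(
    dplyr::group_by(rows, .data$sector, .data$habitat, .data$category),
    mean_cover = mean(.data$cover), .groups = "drop"
  )
  as.data.frame(out)
}
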