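#' Parameters for the synthetic survey generators
#'
#' The generators emulate the field designs behind every pipeline stage:
#' multinomial photo point counts over a fixed benthic category list
#' (10-13 images of 75 points along one 10 x 1 m transect), Poisson
#' parrotfish counts by species/size-bin/phase over two 30 x 4 m belts,
#' Poisson urchin counts by species/size-bin, noisy linear colony growth
#' trajectories, and shoreline TWL tables linear (and monotone) in sea
#' level. Defaults reflect the study conditions: a 2-sector x 3-habitat x
#' 9-site survey, species-mean calcification 29.07 kg m-2 y-1, height
#' extension 6.99 cm y-1, planar-area extension 196.21 cm2 y-1, and 145
#' northern / 71 southern shoreline points.
#'
#' @param cover_probs named probability simplex over benthic categories.
#' @param zone_cover optional named list `"sector.habitat"` -> simplex
#'   overriding `cover_probs` in that zone.
#' @param images_range inclusive range of images per transect.
#' @param points_per_image classified points per image.
#' @param fish_lambda data.frame (`species`, `size_bin`, `phase`,
#'   `lambda`): Poisson mean count per belt transect.
#' @param urchin_lambda data.frame (`species`, `size_bin`, `lambda`):
#'   Poisson mean count per benthic transect.
#' @param calcification_rate,height_rate,area_rate true colony growth
#'   rates (kg m-2 y-1, cm y-1, cm2 y-1).
#' @param growth_noise_sd named vector of observation noise SDs:
#'   `mass` (g, buoyant), `height` (cm), `diameter` (cm).
#' @param visit_survival per-visit colony survival probability.
#' @param twl_base named vector of baseline TWLs (m) per storm.
#' @param twl_slope TWL increase per m of sea-level rise.
#' @param twl_noise_sd alongshore point-to-point SD (m).
#' @return List of class `synth_params`.
#' @export
synth_params <- function(
    cover_probs = c(acropora_palmata = 0.02, pseudodiploria = 0.02,
                    orbicella = 0.02, millepora = 0.01,
                    porites_astreoides = 0.01, cca = 0.05,
                    dead_coral = 0.37, sand = 0.30, macroalgae = 0.15,
                    other = 0.05),
    zone_cover = NULL,
    images_range = c(10, 13),
    points_per_image = 75,
    fish_lambda = data.frame(
      species = c("sparisoma_viride", "sparisoma_viride",
                  "scarus_vetula", "sparisoma_aurofrenatum"),
      size_bin = c(150, 225, 150, 120),
      phase = c("initial", "terminal", "initial", "initial"),
      lambda = c(3, 2, 1.5, 2)
    ),
    urchin_lambda = data.frame(
      species = c("echinometra_lucunter", "diadema_antillarum"),
      size_bin = c(40, 60),
      lambda = c(3, 0.5)
    ),
    calcification_rate = 29.07,
    height_rate = 6.99,
    area_rate = 196.21,
    growth_noise_sd = c(mass = 2, height = 0.3, diameter = 0.2),
    visit_survival = 0.97,
    twl_base = c("10yr" = 3.8, "50yr" = 4.5),
    twl_slope = 1.0,
    twl_noise_sd = 0.3) {
  if (abs(sum(cover_probs) - 1) > 1e-9) {
    stop("cover_probs must sum to 1")
  }
  if (any(cover_probs < 0) || any(fish_lambda$lambda < 0) ||
      any(urchin_lambda$lambda < 0) || any(growth_noise_sd < 0) ||
      twl_noise_sd < 0) {
    stop("probabilities, lambdas and noise SDs must be >= 0")
  }
  structure(
    list(cover_probs = cover_probs, zone_cover = zone_cover,
         images_range = images_range,
         points_per_image = points_per_image,
         fish_lambda = fish_lambda, urchin_lambda = urchin_lambda,
         calcification_rate = calcification_rate,
         height_rate = height_rate, area_rate = area_rate,
         growth_noise_sd = growth_noise_sd,
         visit_survival = visit_survival,
         twl_base = twl_base, twl_slope = twl_slope,
         twl_noise_sd = twl_noise_sd),
    class = "synth_params"
  )
}

# Deterministic largest-remainder allocation of n points to probabilities
allocate_points <- function(n, probs) {
  raw <- n * probs
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  counts
}

#' Generate a synthetic reef census with known ground truth
#'
#' Emulates the stratified survey design: `n_per_zone` sites in each of
#' the six sector/habitat zones. Point counts are multinomial draws from
#' the zone's cover simplex; fish and urchin counts are Poisson draws
#' from the configured per-transect means. With `exact = TRUE` the draws
#' are replaced by deterministic expectations (largest-remainder point
#' allocation, rounded Poisson means), so realized covers and counts
#' equal the recorded truth and budgets can be checked against
#' closed-form oracles.
#'
#' @param params a `synth_params`.
#' @param n_per_zone sites per sector/habitat zone (default 9, i.e. 54
#'   sites).
#' @param seed RNG seed (required; fixed seed gives identical output).
#' @param exact deterministic zero-noise mode (see above).
#' @return List: `censuses` (list of `site_census`), `truth` (per-site
#'   realized cover matrix, fish/urchin count tables, and the generating
#'   `params`).
#' @export
gen_census <- function(params, n_per_zone = 9, seed, exact = FALSE) {
  if (n_per_zone < 1) stop("n_per_zone must be >= 1")
  set.seed(seed)
  zones <- expand.grid(sector = c("northern", "southern"),
                       habitat = c("fore_reef", "reef_crest",
                                   "back_reef"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  categories <- names(params$cover_probs)
  censuses <- list()
  truth_cover <- list()
  site_no <- 0
  for (zi in seq_len(nrow(zones))) {
    zone <- zones[zi, ]
    key <- paste(zone$sector, zone$habitat, sep = ".")
    probs <- params$zone_cover[[key]] %||% params$cover_probs
    for (k in seq_len(n_per_zone)) {
      site_no <- site_no + 1
      site_id <- sprintf("S%02d", site_no)
      n_images <- if (exact) params$images_range[1] else
        params$images_range[1] +
          sample.int(diff(params$images_range) + 1, 1) - 1
      img_counts <- vapply(seq_len(n_images), function(i) {
        if (exact) {
          allocate_points(params$points_per_image, probs)
        } else {
          as.numeric(stats::rmultinom(1, params$points_per_image,
                                      probs))
        }
      }, numeric(length(categories)))
      benthic <- data.frame(
        image = rep(seq_len(n_images), each = length(categories)),
        category = rep(categories, times = n_images),
        count = as.vector(img_counts)
      )
      fl <- params$fish_lambda
      fish <- do.call(rbind, lapply(1:2, function(tr) {
        counts <- if (exact) round(fl$lambda) else
          stats::rpois(nrow(fl), fl$lambda)
        data.frame(transect = tr, species = fl$species,
                   size_bin = fl$size_bin, phase = fl$phase,
                   count = counts)
      }))
      ul <- params$urchin_lambda
      urchins <- data.frame(
        species = ul$species, size_bin = ul$size_bin,
        count = if (exact) round(ul$lambda) else
          stats::rpois(nrow(ul), ul$lambda)
      )
      cs <- site_census(site_id, zone$sector, zone$habitat,
                        benthic, fish, urchins,
                        points_per_image = params$points_per_image)
      censuses[[site_id]] <- cs
      truth_cover[[site_id]] <- cover_from_points(cs)
    }
  }
  truth <- list(
    params = params,
    layout = zones,
    n_per_zone = n_per_zone,
    cover = do.call(rbind, truth_cover),
    fish_counts = if (exact) round(params$fish_lambda$lambda) else NULL,
    urchin_counts = if (exact) round(params$urchin_lambda$lambda) else
      NULL
  )
  list(censuses = censuses, truth = truth)
}

#' Generate synthetic coral growth-assay records
#'
#' Colonies grow linearly in planar area, height and integrated dry mass
#' at the configured true rates; Gaussian observation noise is added to
#' buoyant masses, heights and caliper diameters, and colonies die
#' between visits with probability 1 - `visit_survival` (dead colonies
#' keep a final `"dead"` record and are excluded from rate summaries).
#' Dry mass accumulates as rate x integrated planar area, so with zero
#' noise the first-to-last calcification estimate recovers the true rate
#' exactly.
#'
#' @param params a `synth_params`.
#' @param n_colonies number of colonies (default 30).
#' @param n_visits visits per colony, 0.5 y apart (default 5).
#' @param seed RNG seed.
#' @param species species label for the records.
#' @return List: `records` (growth-record data.frame) and `truth` (the
#'   generating rates).
#' @export
gen_growth <- function(params, n_colonies = 30, n_visits = 5, seed,
                       species = "acropora_palmata") {
  if (n_colonies < 1 || n_visits < 2) {
    stop("need n_colonies >= 1 and n_visits >= 2")
  }
  set.seed(seed)
  rho_sw <- 1.023
  rho_sk <- 2.93
  times <- (seq_len(n_visits) - 1) * 0.5
  sd <- params$growth_noise_sd
  rows <- list()
  for (i in seq_len(n_colonies)) {
    a0 <- 25 + 10 * (i %% 5)           # initial footprint, cm2
    aspect <- 1.4
    h0 <- 8
    m0_dry <- 150                      # initial dry mass, g
    alive <- TRUE
    for (v in seq_len(n_visits)) {
      t <- times[v]
      if (v > 1 && alive &&
          stats::runif(1) > params$visit_survival) {
        alive <- FALSE
      }
      area <- a0 + params$area_rate * t
      # integral of linear area from 0 to t = (a0 + area)/2 * t (cm2 y)
      dry <- m0_dry + params$calcification_rate *
        ((a0 + area) / 2 * t) / 1e4 * 1000   # kg m-2 y-1 over m2 y -> g
      d_max <- sqrt(4 * area / pi * aspect)
      d_min <- sqrt(4 * area / pi / aspect)
      height <- h0 + params$height_rate * t
      noise <- function(s) if (s > 0) stats::rnorm(1, 0, s) else 0
      rows[[length(rows) + 1]] <- data.frame(
        colony_id = sprintf("C%03d", i), species = species,
        station = c("north", "west", "south")[(i %% 3) + 1],
        time = t,
        buoyant_mass = max(dry * (1 - rho_sw / rho_sk) +
                             noise(sd[["mass"]]), 1e-3),
        height = height + noise(sd[["height"]]),
        d_max = d_max + abs(noise(sd[["diameter"]])),
        d_min = d_min - abs(noise(sd[["diameter"]])),
        status = if (alive) "alive" else "dead"
      )
      if (!alive) break
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  list(records = records,
       truth = list(calcification_rate = params$calcification_rate,
                    height_rate = params$height_rate,
                    area_rate = params$area_rate,
                    rho_seawater = rho_sw, rho_skeleton = rho_sk))
}

#' Generate a synthetic shoreline TWL table
#'
#' max_twl = base(storm) + slope x slr + point effect, with a fixed
#' alongshore Gaussian point effect (shared across offsets and storms at
#' each point), so the table is monotone in sea level by construction.
#'
#' @param params a `synth_params`.
#' @param n_north,n_south shoreline points per sector (defaults 145/71,
#'   the study's shoreline discretisation).
#' @param seed RNG seed.
#' @param offsets tabulated sea-level offsets (m).
#' @return List: `table` (a validated `twl_table`) and `truth`.
#' @export
gen_twl <- function(params, n_north = 145, n_south = 71, seed,
                    offsets = c(0.0, 0.2, 0.5, 1.2, 2.0)) {
  set.seed(seed)
  pts <- data.frame(
    point_id = sprintf("P%03d", seq_len(n_north + n_south)),
    sector = rep(c("northern", "southern"), c(n_north, n_south))
  )
  pts$effect <- if (params$twl_noise_sd > 0) {
    stats::rnorm(nrow(pts), 0, params$twl_noise_sd)
  } else {
    0
  }
  grid <- expand.grid(i = seq_len(nrow(pts)),
                      storm = names(params$twl_base),
                      slr_offset = offsets,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- data.frame(
    point_id = pts$point_id[grid$i],
    sector = pts$sector[grid$i],
    storm = grid$storm,
    slr_offset = grid$slr_offset,
    max_twl = params$twl_base[grid$storm] +
      params$twl_slope * grid$slr_offset + pts$effect[grid$i]
  )
  rownames(tab) <- NULL
  list(table = validate_twl(tab, offsets),
       truth = list(base = params$twl_base, slope = params$twl_slope,
                    noise_sd = params$twl_noise_sd,
                    point_effects = pts))
}
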