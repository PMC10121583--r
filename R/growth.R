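#' Planar footprint area of a colony from caliper diameters
#'
#' The footprint is treated as an ellipse with the measured maximum and
#' minimum planar diameters: area = pi/4 * d_max * d_min.
#'
#' @param d_max,d_min diameters in cm, `d_max >= d_min > 0`.
#' @return cm2.
#' @export
ellipse_area <- function(d_max, d_min) {
  if (any(d_max <= 0) || any(d_min <= 0)) {
    stop("diameters must be positive")
  }
  if (any(d_max < d_min)) stop("d_max must be >= d_min")
  pi / 4 * d_max * d_min
}

#' Dry skeletal mass from buoyant weight
#'
#' Archimedes: m_dry = m_buoyant / (1 - rho_seawater / rho_skeleton).
#' Defaults are standard buoyant-weighing practice for aragonite skeletons
#' in tropical seawater and are overridable.
#'
#' @param buoyant_mass g.
#' @param rho_seawater g cm-3 (default 1.023).
#' @param rho_skeleton g cm-3 (aragonite, default 2.93).
#' @return Dry mass in g.
#' @export
buoyant_to_dry <- function(buoyant_mass, rho_seawater = 1.023,
                           rho_skeleton = 2.93) {
  if (rho_seawater < 0 || rho_skeleton <= rho_seawater) {
    stop("need rho_skeleton > rho_seawater >= 0")
  }
  buoyant_mass / (1 - rho_seawater / rho_skeleton)
}

#' Growth-assay measurement records
#'
#' One row per colony visit: `colony_id`, `species`, `station`, `time`
#' (Date or decimal year), `buoyant_mass` (g), `height` (cm), `d_max`,
#' `d_min` (cm), `status` (`"alive"`, `"partial_mortality"`, `"dead"`).
#'
#' @param path CSV file.
#' @return data.frame with times parsed and per-colony ordering checked.
#' @export
read_growth_records <- function(path) {
  if (!file.exists(path)) stop("growth records file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("colony_id", "species", "station", "time", "buoyant_mass",
              "height", "d_max", "d_min", "status")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("growth records missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!all(df$status %in% c("alive", "partial_mortality", "dead"))) {
    stop("status must be alive, partial_mortality or dead")
  }
  alive <- df$status != "dead"
  if (any(df$buoyant_mass[alive] <= 0)) {
    stop("buoyant mass must be positive while alive")
  }
  if (any(df$d_max < df$d_min)) stop("d_max must be >= d_min")
  ord <- order(df$colony_id, df$time)
  df <- df[ord, ]
  by_col <- split(df$time, df$colony_id)
  bad <- names(by_col)[vapply(by_col,
                              function(t) any(diff(t) <= 0), logical(1))]
  if (length(bad) > 0) {
    stop("non-increasing visit times for colony: ",
         paste(bad, collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

years_between <- function(t0, t1) {
  if (inherits(t0, "Date") || inherits(t1, "Date")) {
    as.numeric(as.Date(t1) - as.Date(t0)) / 365.25
  } else {
    as.numeric(t1) - as.numeric(t0)
  }
}

#' Calcification rate between two visits of one colony
#'
#' (dry-mass change in kg) / (normalizing planar area in m2) / (elapsed
#' years). The normalizing area is, by `area_mode`, the interval mean of
#' the start and end elliptical footprints (default), or the start or end
#' footprint alone.
#'
#' @param rec0,rec1 single growth-record rows (`rec1` later).
#' @param area_mode `"mean"`, `"start"` or `"end"`.
#' @param rho_seawater,rho_skeleton passed to [buoyant_to_dry()].
#' @return List: `rate` (kg m-2 y-1) and `dead_endpoint` flag (a dead
#'   endpoint yields `NA` rate; such intervals are excluded from
#'   summaries).
#' @export
calcification_rate <- function(rec0, rec1, area_mode = c("mean", "start",
                                                         "end"),
                               rho_seawater = 1.023,
                               rho_skeleton = 2.93) {
  area_mode <- match.arg(area_mode)
  dt <- years_between(rec0$time, rec1$time)
  if (dt <= 0) stop("visits must be strictly ordered in time")
  if (rec0$status == "dead" || rec1$status == "dead") {
    return(list(rate = NA_real_, dead_endpoint = TRUE))
  }
  dm_kg <- (buoyant_to_dry(rec1$buoyant_mass, rho_seawater, rho_skeleton) -
              buoyant_to_dry(rec0$buoyant_mass, rho_seawater,
                             rho_skeleton)) / 1000
  a0 <- ellipse_area(rec0$d_max, rec0$d_min)
  a1 <- ellipse_area(rec1$d_max, rec1$d_min)
  area_cm2 <- switch(area_mode, mean = (a0 + a1) / 2, start = a0,
                     end = a1)
  list(rate = dm_kg / (area_cm2 / 1e4) / dt, dead_endpoint = FALSE)
}

#' Height- and planar-area extension rates between two visits
#'
#' Finite differences over the elapsed time; negative values are allowed
#' (partial-mortality shrinkage).
#'
#' @inheritParams calcification_rate
#' @return Named vector `c(height = cm y-1, area = cm2 y-1)`.
#' @export
extension_rates <- function(rec0, rec1) {
  dt <- years_between(rec0$time, rec1$time)
  if (dt <= 0) stop("visits must be strictly ordered in time")
  c(height = (rec1$height - rec0$height) / dt,
    area = (ellipse_area(rec1$d_max, rec1$d_min) -
              ellipse_area(rec0$d_max, rec0$d_min)) / dt)
}

#' Per-colony growth rates over a full record set
#'
#' Computes, for every colony, the calcification and extension rates over
#' its first-to-last alive interval. Colonies with complete mortality are
#' excluded.
#'
#' @param records data.frame as returned by [read_growth_records()].
#' @inheritParams calcification_rate
#' @return data.frame: colony_id, species, station, calcification
#'   (kg m-2 y-1), height_rate (cm y-1), area_rate (cm2 y-1).
#' @export
growth_rates <- function(records, area_mode = "mean",
                         rho_seawater = 1.023, rho_skeleton = 2.93) {
  rows <- lapply(split(records, records$colony_id), function(df) {
    df <- df[order(df$time), ]
    if (df$status[nrow(df)] == "dead") return(NULL)
    alive <- df[df$status != "dead", ]
    if (nrow(alive) < 2) return(NULL)
    r0 <- alive[1, ]
    r1 <- alive[nrow(alive), ]
    calc <- calcification_rate(r0, r1, area_mode, rho_seawater,
                               rho_skeleton)
    ext <- extension_rates(r0, r1)
    data.frame(colony_id = df$colony_id[1], species = df$species[1],
               station = df$station[1], calcification = calc$rate,
               height_rate = unname(ext[["height"]]),
               area_rate = unname(ext[["area"]]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Species-level growth summaries
#'
#' Mean and standard error of each rate, by species, using either
#' colony-level averaging (each colony one observation, default) or
#' station-level averaging (station means first, then averaged).
#'
#' @param rates data.frame from [growth_rates()].
#' @param level `"colony"` or `"station"`.
#' @return data.frame: species, n, and mean/se for calcification,
#'   height_rate and area_rate.
#' @export
summarise_growth <- function(rates, level = c("colony", "station")) {
  level <- match.arg(level)
  if (level == "station") {
    rates <- as.data.frame(dplyr::summarise(
      dplyr::group_by(rates, .data$species, .data$station),
      calcification = mean(.data$calcification),
      height_rate = mean(.data$height_rate),
      area_rate = mean(.data$area_rate), .groups = "drop"
    ))
  }
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  as.data.frame(dplyr::summarise(
    dplyr::group_by(rates, .data$species),
    n = dplyr::n(),
    calcification_mean = mean(.data$calcification),
    calcification_se = se(.data$calcification),
    height_rate_mean = mean(.data$height_rate),
    height_rate_se = se(.data$height_rate),
    area_rate_mean = mean(.data$area_rate),
    area_rate_se = se(.data$area_rate),
    .groups = "drop"
  ))
}
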