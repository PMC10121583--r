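#' Shoreline total-water-level tables
#'
#' TWL tables are an input contract: they are produced offline by a
#' hydrodynamic wave model run at a fixed set of sea-level offsets and two
#' storm return periods, and this package only post-processes them. One
#' row per (point, storm, offset): `point_id`, `sector`
#' (`"northern"`/`"southern"`), `storm` (`"10yr"`/`"50yr"`), `slr_offset`
#' (m), `max_twl` (m), optionally `wave_driven` (m).
#'
#' @param path CSV file.
#' @param offsets the sea-level offsets every (point, storm) pair must
#'   cover.
#' @return Validated data.frame (class also `twl_table`).
#' @export
read_twl <- function(path, offsets = c(0.0, 0.2, 0.5, 1.2, 2.0)) {
  if (!file.exists(path)) stop("TWL file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_twl(df, offsets)
}

#' @rdname read_twl
#' @param df a data.frame to validate in place of a file.
#' @export
validate_twl <- function(df, offsets = c(0.0, 0.2, 0.5, 1.2, 2.0)) {
  needed <- c("point_id", "sector", "storm", "slr_offset", "max_twl")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("TWL table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(df$sector %in% c("northern", "southern"))) {
    stop("sector must be northern or southern")
  }
  for (grp in split(df, list(df$point_id, df$storm), drop = TRUE)) {
    if (!setequal(grp$slr_offset, offsets)) {
      stop("point ", grp$point_id[1], " storm ", grp$storm[1],
           " does not cover all sea-level offsets")
    }
    ord <- order(grp$slr_offset)
    if (is.unsorted(grp$max_twl[ord])) {
      stop("max_twl must be non-decreasing in slr_offset at point ",
           grp$point_id[1], " storm ", grp$storm[1])
    }
  }
  class(df) <- unique(c("twl_table", class(df)))
  df
}

#' Interpolate the total water level at an arbitrary sea level
#'
#' Piecewise-linear interpolation between the tabulated sea-level
#' offsets; exact at the nodes. Requests outside the tabulated range are
#' errors — the wave-model table bounds are hard limits and no
#' extrapolation is performed.
#'
#' @param table a `twl_table`.
#' @param point point_id.
#' @param storm `"10yr"` or `"50yr"`.
#' @param slr sea level (m) at which to evaluate.
#' @return Interpolated maximum TWL (m).
#' @export
interp_twl <- function(table, point, storm, slr) {
  rows <- table[table$point_id == point & table$storm == storm, ]
  if (nrow(rows) == 0) {
    stop("no TWL records for point ", point, " storm ", storm)
  }
  rows <- rows[order(rows$slr_offset), ]
  if (slr < min(rows$slr_offset) - 1e-12 ||
      slr > max(rows$slr_offset) + 1e-12) {
    stop("sea level ", slr, " m outside the tabulated range [",
         min(rows$slr_offset), ", ", max(rows$slr_offset),
         "]; no extrapolation")
  }
  stats::approx(rows$slr_offset, rows$max_twl, xout = slr,
                rule = 1)$y
}

#' Total water level under a restoration-adjusted sea level
#'
#' Reef accretion through restoration raises the reef crest by
#' `elevation_gain`, which offsets the sea-level scenario: the effective
#' sea level is max(slr - gain, 0), clamped so that the returned TWL
#' never drops below the table's +0.0 scenario (the wave model was not
#' run at lower-than-present water depths).
#'
#' @param table a `twl_table`.
#' @param point,storm as in [interp_twl()].
#' @param slr scenario sea-level rise (m).
#' @param elevation_gain projected reef-elevation gain (m, >= 0); supply
#'   the gain of the point's sector.
#' @return Adjusted maximum TWL (m).
#' @export
restoration_adjusted_twl <- function(table, point, storm, slr,
                                     elevation_gain) {
  if (elevation_gain < 0) stop("elevation_gain must be >= 0")
  interp_twl(table, point, storm, max(slr - elevation_gain, 0))
}

#' Adjusted TWLs for every shoreline point
#'
#' Applies [restoration_adjusted_twl()] across the whole table at one
#' scenario sea level, with sector-specific elevation gains (the
#' northern and southern reef crest are projected separately).
#'
#' @param table a `twl_table`.
#' @param slr scenario sea-level rise (m).
#' @param gains named vector `c(northern = , southern = )` of
#'   reef-elevation gains (m).
#' @param storms storms to process (default both).
#' @return data.frame: point_id, sector, storm, slr, effective_slr,
#'   max_twl (adjusted).
#' @export
adjust_twl_table <- function(table, slr, gains,
                             storms = c("10yr", "50yr")) {
  pts <- unique(table[, c("point_id", "sector")])
  out <- do.call(rbind, lapply(storms, function(st) {
    do.call(rbind, lapply(seq_len(nrow(pts)), function(i) {
      p <- pts[i, ]
      gain <- gains[[p$sector]]
      if (is.null(gain)) stop("no elevation gain for sector ", p$sector)
      data.frame(
        point_id = p$point_id, sector = p$sector, storm = st,
        slr = slr, effective_slr = max(slr - gain, 0),
        max_twl = restoration_adjusted_twl(table, p$point_id, st, slr,
                                           gain)
      )
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Alongshore mean and standard error of total water levels
#'
#' Averages TWLs over shoreline points within each (sector, storm,
#' sea-level) group. For restoration runs, the reported uncertainty is
#' the root-sum-square of the alongshore TWL standard error and the
#' standard error of the projected reef-elevation change.
#'
#' @param twl data.frame with columns `sector`, `storm`, `max_twl` and a
#'   sea-level column (`slr_offset` or `slr`).
#' @param elev_se optional named vector `c(northern = , southern = )` of
#'   reef-elevation-change SEs (m); when given, `combined_se` =
#'   sqrt(se_twl^2 + se_elev^2).
#' @return data.frame: sector, storm, slr, n, mean_twl, se_twl and, when
#'   `elev_se` is supplied, combined_se.
#' @export
alongshore_summary <- function(twl, elev_se = NULL) {
  slr_col <- if ("slr_offset" %in% names(twl)) "slr_offset" else "slr"
  twl$.slr <- twl[[slr_col]]
  if (nrow(twl) == 0) stop("empty TWL table")
  out <- as.data.frame(dplyr::summarise(
    dplyr::group_by(twl, .data$sector, .data$storm, .data$.slr),
    n = dplyr::n(),
    mean_twl = mean(.data$max_twl),
    se_twl = stats::sd(.data$max_twl) / sqrt(dplyr::n()),
    .groups = "drop"
  ))
  names(out)[names(out) == ".slr"] <- "slr"
  if (any(out$n < 2)) {
    stop("need >= 2 shoreline points per group for a standard error")
  }
  if (!is.null(elev_se)) {
    out$combined_se <- sqrt(out$se_twl^2 +
                              unname(elev_se[out$sector])^2)
  }
  out
}
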