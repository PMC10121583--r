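#' A single reef-census site
#'
#' Bundles the three field surveys conducted at one stratified-random site:
#' benthic photo point counts along one 10 x 1 m transect (10-13 images,
#' a fixed number of classified points per image), parrotfish counts by
#' species, 15-mm fork-length bin and life phase on two 30 x 4 m belt
#' transects, and urchin counts by species and 20-mm test-size bin along
#' the benthic transect. Sites are labelled by reef sector (windward
#' southern vs leeward northern) and habitat zone (fore reef, reef crest,
#' back reef).
#'
#' @param site_id site label.
#' @param sector `"northern"` or `"southern"`.
#' @param habitat `"fore_reef"`, `"reef_crest"` or `"back_reef"`.
#' @param benthic_points data.frame with columns `image` (integer),
#'   `category`, `count`; every image's counts must sum to
#'   `points_per_image`.
#' @param fish_counts data.frame with columns `transect` (1 or 2),
#'   `species`, `size_bin` (15-mm bin lower edge, mm), `phase`
#'   (`"initial"`/`"terminal"`), `count`. Both transects must be present
#'   (a transect with no fish still appears via a zero-count row).
#' @param urchin_counts data.frame with columns `species`, `size_bin`
#'   (20-mm bin lower edge, mm), `count`.
#' @param points_per_image classified points per image (default 75).
#' @param benthic_transect_area m2 surveyed for benthos/urchins
#'   (default 10).
#' @param fish_belt_area m2 per fish belt transect (default 120).
#' @return An object of class `site_census`.
#' @export
site_census <- function(site_id, sector, habitat,
                        benthic_points, fish_counts, urchin_counts,
                        points_per_image = 75,
                        benthic_transect_area = 10,
                        fish_belt_area = 120) {
  sector <- match.arg(sector, c("northern", "southern"))
  habitat <- match.arg(habitat, c("fore_reef", "reef_crest", "back_reef"))
  benthic_points <- as.data.frame(benthic_points)
  fish_counts <- as.data.frame(fish_counts)
  urchin_counts <- as.data.frame(urchin_counts)

  check_counts <- function(x, what) {
    if (any(x$count < 0) || any(x$count != round(x$count))) {
      stop("site ", site_id, ": ", what, " counts must be non-negative ",
           "integers", call. = FALSE)
    }
  }
  if (nrow(benthic_points) == 0) {
    stop("site ", site_id, ": benthic_points is empty", call. = FALSE)
  }
  check_counts(benthic_points, "benthic")
  check_counts(fish_counts, "fish")
  check_counts(urchin_counts, "urchin")

  per_image <- tapply(benthic_points$count, benthic_points$image, sum)
  bad <- per_image != points_per_image
  if (any(bad)) {
    stop("site ", site_id, ": image(s) ",
         paste(names(per_image)[bad], collapse = ", "),
         " tally ", paste(per_image[bad], collapse = ", "),
         " points, expected ", points_per_image, call. = FALSE)
  }
  if (nrow(fish_counts) > 0) {
    if (!setequal(unique(fish_counts$transect), c(1, 2))) {
      stop("site ", site_id, ": exactly two fish belt transects required",
           call. = FALSE)
    }
    if (any(fish_counts$size_bin %% 15 != 0)) {
      stop("site ", site_id, ": fish size bins must be multiples of 15 mm",
           call. = FALSE)
    }
    if (!all(fish_counts$phase %in% c("initial", "terminal"))) {
      stop("site ", site_id, ": fish phase must be initial or terminal",
           call. = FALSE)
    }
  }
  if (nrow(urchin_counts) > 0 && any(urchin_counts$size_bin %% 20 != 0)) {
    stop("site ", site_id, ": urchin size bins must be multiples of 20 mm",
         call. = FALSE)
  }

  structure(
    list(site_id = as.character(site_id), sector = sector,
         habitat = habitat, benthic_points = benthic_points,
         fish_counts = fish_counts, urchin_counts = urchin_counts,
         points_per_image = points_per_image,
         benthic_transect_area = benthic_transect_area,
         fish_belt_area = fish_belt_area),
    class = "site_census"
  )
}

#' @export
print.site_census <- function(x, ...) {
  cat("<site_census>", x$site_id, "-", x$sector, x$habitat, "\n")
  cat("  images:", length(unique(x$benthic_points$image)),
      "x", x$points_per_image, "points;",
      sum(x$fish_counts$count), "parrotfish;",
      sum(x$urchin_counts$count), "urchins\n")
  invisible(x)
}

#' Percent cover from photo point counts
#'
#' Pools point tallies across all images of the site's benthic transect:
#' cover of category t is (points of t) / (total points). Pooling makes
#' the estimate invariant to how the same tallies are partitioned into
#' images.
#'
#' @param census a `site_census`.
#' @param as_percent return percentages instead of fractions
#'   (fractions are the internal convention; percent is an I/O rendering).
#' @return Named numeric vector of cover fractions summing to 1 (or
#'   percentages summing to 100).
#' @export
cover_from_points <- function(census, as_percent = FALSE) {
  bp <- census$benthic_points
  total <- sum(bp$count)
  if (total == 0) stop("site ", census$site_id, ": zero total points")
  by_cat <- tapply(bp$count, bp$category, sum)
  cover <- as.numeric(by_cat) / total
  names(cover) <- names(by_cat)
  if (as_percent) cover * 100 else cover
}

census_file_paths <- function(dir) {
  stats::setNames(
    file.path(dir, c("benthic.csv", "fish.csv", "urchins.csv",
                     "sites.csv")),
    c("benthic", "fish", "urchins", "sites")
  )
}

#' Write a collection of site censuses as CSV tables
#'
#' Four comma-delimited UTF-8 files are written under `dir`: `sites.csv`
#' (site_id, sector, habitat, points_per_image, benthic_transect_area,
#' fish_belt_area), `benthic.csv` (one row per site/image/category),
#' `fish.csv` (one row per site/transect/species/size_bin/phase) and
#' `urchins.csv` (one row per site/species/size_bin). [read_census()]
#' round-trips this layout exactly.
#'
#' @param censuses list of `site_census` objects.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_census <- function(censuses, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- census_file_paths(dir)
  sites <- do.call(rbind, lapply(censuses, function(cs) {
    data.frame(site_id = cs$site_id, sector = cs$sector,
               habitat = cs$habitat,
               points_per_image = cs$points_per_image,
               benthic_transect_area = cs$benthic_transect_area,
               fish_belt_area = cs$fish_belt_area)
  }))
  bind_with_id <- function(field) {
    do.call(rbind, lapply(censuses, function(cs) {
      df <- cs[[field]]
      if (nrow(df) == 0) return(NULL)
      cbind(site_id = cs$site_id, df)
    }))
  }
  utils::write.csv(sites, paths[["sites"]], row.names = FALSE)
  utils::write.csv(bind_with_id("benthic_points"), paths[["benthic"]],
                   row.names = FALSE)
  utils::write.csv(bind_with_id("fish_counts"), paths[["fish"]],
                   row.names = FALSE)
  utils::write.csv(bind_with_id("urchin_counts"), paths[["urchins"]],
                   row.names = FALSE)
  invisible(dir)
}

read_component <- function(path, required, what) {
  if (!file.exists(path)) stop("census file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("census ", what, " table ", basename(path),
         " is missing column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' Read a census directory written by [write_census()]
#'
#' @param dir directory containing `sites.csv`, `benthic.csv`, `fish.csv`,
#'   `urchins.csv`.
#' @return List of validated `site_census` objects, in `sites.csv` row
#'   order. Schema problems name the offending column; invariant breaches
#'   name the offending site.
#' @export
read_census <- function(dir) {
  paths <- census_file_paths(dir)
  sites <- read_component(paths[["sites"]],
                          c("site_id", "sector", "habitat"), "site")
  benthic <- read_component(paths[["benthic"]],
                            c("site_id", "image", "category", "count"),
                            "benthic")
  fish <- read_component(paths[["fish"]],
                         c("site_id", "transect", "species", "size_bin",
                           "phase", "count"), "fish")
  urchins <- read_component(paths[["urchins"]],
                            c("site_id", "species", "size_bin", "count"),
                            "urchin")
  lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    site_census(
      site_id = s$site_id, sector = s$sector, habitat = s$habitat,
      benthic_points = benthic[benthic$site_id == s$site_id,
                               c("image", "category", "count")],
      fish_counts = fish[fish$site_id == s$site_id,
                         c("transect", "species", "size_bin", "phase",
                           "count")],
      urchin_counts = urchins[urchins$site_id == s$site_id,
                              c("species", "size_bin", "count")],
      points_per_image = s$points_per_image %||% 75,
      benthic_transect_area = s$benthic_transect_area %||% 10,
      fish_belt_area = s$fish_belt_area %||% 120
    )
  })
}
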