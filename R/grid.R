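#' Read an ESRI ASCII raster grid
#'
#' Minimal plain-text grid support for the zonal bathymetry adjustment:
#' the six-line header (ncols, nrows, xllcorner, yllcorner, cellsize,
#' NODATA_value) followed by nrows rows of ncols values, top row first.
#' NODATA cells become `NA`.
#'
#' @param path .asc file.
#' @return Numeric matrix (rows top-to-bottom) with attributes
#'   `xllcorner`, `yllcorner`, `cellsize`, `nodata`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("grid file not found: ", path)
  lines <- readLines(path)
  header <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    header[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  for (k in c("ncols", "nrows")) {
    if (is.null(header[[k]])) stop("grid header missing ", k)
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != header$ncols * header$nrows) {
    stop("grid body has ", length(vals), " values, expected ",
         header$ncols * header$nrows)
  }
  m <- matrix(vals, nrow = header$nrows, ncol = header$ncols, byrow = TRUE)
  nodata <- header$nodata_value %||% -9999
  m[m == nodata] <- NA
  attr(m, "xllcorner") <- header$xllcorner %||% 0
  attr(m, "yllcorner") <- header$yllcorner %||% 0
  attr(m, "cellsize") <- header$cellsize %||% 1
  attr(m, "nodata") <- nodata
  m
}

#' Write an ESRI ASCII raster grid
#'
#' @param grid numeric matrix (`NA` written as the nodata value).
#' @param path output path.
#' @param xllcorner,yllcorner,cellsize,nodata header values; defaults are
#'   taken from the matrix attributes when present.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, xllcorner = NULL,
                             yllcorner = NULL, cellsize = NULL,
                             nodata = NULL) {
  xllcorner <- xllcorner %||% attr(grid, "xllcorner") %||% 0
  yllcorner <- yllcorner %||% attr(grid, "yllcorner") %||% 0
  cellsize <- cellsize %||% attr(grid, "cellsize") %||% 1
  nodata <- nodata %||% attr(grid, "nodata") %||% -9999
  body <- grid
  body[is.na(body)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(grid)), paste("nrows", nrow(grid)),
    paste("xllcorner", xllcorner), paste("yllcorner", yllcorner),
    paste("cellsize", cellsize), paste("NODATA_value", nodata)
  ), con)
  utils::write.table(body, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Shift bathymetry by zone-specific elevation changes
#'
#' Adds the projected elevation change (m, positive up) of each habitat
#' zone to every bathymetry cell labelled with that zone. Cells labelled
#' `"none"` (or `NA`) are left unchanged. The two grids must be congruent
#' (same dimensions and, when both carry georeference attributes, the
#' same origin and cell size).
#'
#' @param bathy numeric matrix, elevation in m (positive up).
#' @param zones character matrix of zone labels, congruent with `bathy`.
#' @param deltas named numeric vector, zone label -> elevation change (m).
#' @return Adjusted bathymetry matrix (attributes preserved).
#' @export
apply_zonal_elevation <- function(bathy, zones, deltas) {
  if (!all(dim(bathy) == dim(zones))) {
    stop("bathymetry and zone grids have different shapes: ",
         paste(dim(bathy), collapse = "x"), " vs ",
         paste(dim(zones), collapse = "x"))
  }
  for (at in c("xllcorner", "yllcorner", "cellsize")) {
    a <- attr(bathy, at); b <- attr(zones, at)
    if (!is.null(a) && !is.null(b) && !isTRUE(all.equal(a, b))) {
      stop("bathymetry and zone grids disagree on ", at)
    }
  }
  labels <- unique(as.vector(zones))
  labels <- labels[!is.na(labels) & labels != "none"]
  unknown <- setdiff(labels, names(deltas))
  if (length(unknown) > 0) {
    stop("no elevation change supplied for zone(s): ",
         paste(unknown, collapse = ", "))
  }
  out <- bathy
  for (z in labels) {
    idx <- !is.na(zones) & zones == z
    out[idx] <- out[idx] + deltas[[z]]
  }
  out
}
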