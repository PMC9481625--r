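#' @include AllClasses.R AllGenerics.R
NULL

## Grid conventions, used everywhere:
##  - WGS84 lon/lat degrees, square cells, cell-centre registration
##  - row 1 is the northernmost row
##  - (xll, yll) is the outer corner of the lower-left (south-west) cell
##  - point-in-cell containment is half-open: [west, east) x (south, north]

gridTop <- function(x) x@yll + nrow(x@mask) * x@cellsize

#' Cell-centre coordinates of a gridded object
#'
#' @param x a ClimateStack or SuitabilitySurface
#' @param cells optional integer vector of cell indices (column-major over
#'   the grid matrix); default all cells
#' @return matrix with columns \code{longitude}, \code{latitude}
#' @export
cellCentres <- function(x, cells = NULL) {
  nr <- nrow(x@mask); nc <- ncol(x@mask)
  if (is.null(cells)) cells <- seq_len(nr * nc)
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  lon <- x@xll + (col - 0.5) * x@cellsize
  lat <- gridTop(x) - (row - 0.5) * x@cellsize
  cbind(longitude = lon, latitude = lat)
}

#' Cell indices containing points
#'
#' Maps lon/lat points to column-major cell indices using half-open
#' containment \code{[west, east) x (south, north]}: a point exactly on a
#' shared edge belongs to the cell to its east is excluded from, i.e. the
#' west and north edges are inclusive.
#'
#' @param x a ClimateStack or SuitabilitySurface
#' @param lon,lat numeric vectors of coordinates (degrees)
#' @return integer vector of cell indices; \code{NA} for points outside
#'   the grid extent
#' @export
cellFromXY <- function(x, lon, lat) {
  nr <- nrow(x@mask); nc <- ncol(x@mask)
  top <- gridTop(x)
  col <- floor((lon - x@xll) / x@cellsize) + 1
  row <- floor((top - lat) / x@cellsize) + 1
  row[lat == top] <- 1  # north edge of the grid is inclusive
  out <- row < 1 | row > nr | col < 1 | col > nc
  idx <- (col - 1) * nr + row
  idx[out] <- NA_integer_
  as.integer(idx)
}

## shared geometry check for binary surface/stack operations
stopIfGridMismatch <- function(a, b, what = "objects") {
  if (!identical(dim(a@mask), dim(b@mask)) ||
      abs(a@xll - b@xll) > 1e-9 || abs(a@yll - b@yll) > 1e-9 ||
      abs(a@cellsize - b@cellsize) > 1e-12)
    stop(what, " are on different grids (dims/origin/cellsize mismatch)")
  invisible(TRUE)
}

newSurface <- function(values, template, scale, provenance = list()) {
  new("SuitabilitySurface", values = values, scale = scale,
      mask = template@mask, xll = template@xll, yll = template@yll,
      cellsize = template@cellsize, provenance = provenance)
}
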