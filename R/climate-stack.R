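#' @include AllClasses.R grid-geometry.R ascii-grid.R
NULL

#' Construct a ClimateStack from layer matrices
#'
#' @param layers named list of numeric matrices (row 1 = north), all with
#'   identical dimensions; NA marks NoData
#' @param xll,yll lower-left corner of the grid (degrees)
#' @param cellsize cell edge (degrees)
#' @param nodata NoData sentinel for on-disk representation
#' @param mask optional logical matrix; default: cells non-NA in every layer
#' @return a \linkS4class{ClimateStack}
#' @export
climateStack <- function(layers, xll = 0, yll = 0, cellsize = 1,
                         nodata = -9999, mask = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1L,
            !is.null(names(layers)), all(nzchar(names(layers))))
  d <- dim(layers[[1L]])
  for (nm in names(layers))
    if (!identical(dim(layers[[nm]]), d))
      stop("layer '", nm, "' has mismatched dimensions")
  arr <- array(NA_real_, dim = c(d, length(layers)),
               dimnames = list(NULL, NULL, names(layers)))
  for (k in seq_along(layers)) arr[, , k] <- layers[[k]]
  if (is.null(mask)) {
    mask <- !apply(arr, c(1, 2), anyNA)
  } else {
    stopifnot(identical(dim(mask), d))
  }
  # off-mask cells are NoData in every layer; mask cells must be complete
  if (!all(mask))
    for (k in seq_along(layers)) arr[, , k][!mask] <- NA_real_
  new("ClimateStack", layers = arr, mask = mask, xll = xll, yll = yll,
      cellsize = cellsize, nodata = nodata)
}

#' Read a stack of co-registered ESRI ASCII grids
#'
#' All files must share grid geometry exactly; the study-area mask is the
#' intersection of non-NoData cells across layers.
#'
#' @param paths character vector of raster file paths
#' @param variableNames layer names, same length and order as \code{paths}
#' @return a \linkS4class{ClimateStack} with layers in the given order
#' @export
readRasterStack <- function(paths, variableNames) {
  stopifnot(length(paths) == length(variableNames), length(paths) >= 1L)
  first <- readAsciiGrid(paths[1L])
  layers <- stats::setNames(vector("list", length(paths)), variableNames)
  layers[[1L]] <- first$values
  if (length(paths) > 1L) for (i in 2L:length(paths)) {
    g <- readAsciiGrid(paths[i])
    if (!identical(dim(g$values), dim(first$values)) ||
        abs(g$xll - first$xll) > 1e-9 || abs(g$yll - first$yll) > 1e-9 ||
        abs(g$cellsize - first$cellsize) > 1e-12)
      stop("raster geometry mismatch in file: ", paths[i])
    layers[[i]] <- g$values
  }
  climateStack(layers, xll = first$xll, yll = first$yll,
               cellsize = first$cellsize, nodata = first$nodata)
}

#' Write every layer of a stack as ESRI ASCII grids
#'
#' @param stack a ClimateStack
#' @param dir output directory (created if needed)
#' @param prefix filename prefix; files are \code{<prefix><layer>.asc}
#' @return invisible character vector of written paths
#' @export
writeClimateStack <- function(stack, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nLayers(stack))
  for (k in seq_len(nLayers(stack))) {
    nm <- layerNames(stack)[k]
    paths[k] <- file.path(dir, paste0(prefix, nm, ".asc"))
    writeAsciiGrid(stack@layers[, , k], paths[k], xll = stack@xll,
                   yll = stack@yll, cellsize = stack@cellsize,
                   nodata = stack@nodata)
  }
  invisible(paths)
}

#' Write a suitability surface as an ESRI ASCII grid
#'
#' @param surface a SuitabilitySurface
#' @param path output path
#' @export
writeSurface <- function(surface, path) {
  writeAsciiGrid(surface@values, path, xll = surface@xll,
                 yll = surface@yll, cellsize = surface@cellsize)
}
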