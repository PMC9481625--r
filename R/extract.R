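#' @include AllClasses.R grid-geometry.R
NULL

#' Extract climate values at occurrence points
#'
#' Looks up the grid cell containing each point (half-open containment,
#' see \code{\link{cellFromXY}}) and returns the stack's layer values
#' there. Every point must fall on an unmasked cell.
#'
#' @param stack a ClimateStack
#' @param occ an OccurrenceSet, or a two-column matrix/data.frame of
#'   longitude, latitude
#' @return numeric matrix, one row per point, one column per layer
#' @export
extractValues <- function(stack, occ) {
  pts <- if (is(occ, "OccurrenceSet"))
    as.matrix(occ@records[c("longitude", "latitude")])
  else as.matrix(occ)[, 1:2, drop = FALSE]
  cells <- cellFromXY(stack, pts[, 1], pts[, 2])
  bad <- which(is.na(cells))
  if (length(bad))
    stop("points outside the grid extent (rows ",
         paste(bad, collapse = ", "), ")")
  offmask <- which(!stack@mask[cells])
  if (length(offmask))
    stop("points on masked/NoData cells (rows ",
         paste(offmask, collapse = ", "), ")")
  valuesAtCells(stack, cells)
}

#' Layer values at column-major cell indices
#' @noRd
valuesAtCells <- function(stack, cells) {
  ncell <- prod(gridDim(stack))
  out <- vapply(seq_len(nLayers(stack)),
                function(k) stack@layers[, , k][cells],
                numeric(length(cells)))
  out <- matrix(out, nrow = length(cells), ncol = nLayers(stack))
  colnames(out) <- layerNames(stack)
  out
}

#' Sample background cells uniformly from the study area
#'
#' Draws \code{n} unmasked cells uniformly without replacement and returns
#' their climate values and indices. Deterministic given \code{seed}.
#'
#' @param stack a ClimateStack
#' @param n number of background points (must not exceed the number of
#'   unmasked cells)
#' @param seed integer RNG seed
#' @return list with \code{values} (n x nLayers matrix), \code{cells}
#'   (column-major cell indices), \code{coords} (cell-centre lon/lat)
#' @export
sampleBackground <- function(stack, n, seed) {
  avail <- which(stack@mask)
  if (n > length(avail))
    stop(sprintf("requested %d background points but only %d unmasked cells",
                 n, length(avail)))
  cells <- withSeed(seed, {
    if (n == length(avail)) avail else sort(sample(avail, n))
  })
  list(values = valuesAtCells(stack, cells), cells = cells,
       coords = cellCentres(stack, cells))
}
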