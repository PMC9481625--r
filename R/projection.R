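#' @include AllClasses.R maxent-predict.R grid-geometry.R
NULL

#' Project a fitted model onto another climate stack
#'
#' Runs \code{\link{predictSurface}} on the new stack (clamping on by
#' default, as when transferring to novel climates) and attaches a
#' companion clamping mask marking cells where any scaled feature left
#' the training range.
#'
#' @param model a MaxentModel
#' @param newStack a ClimateStack carrying all model variables
#' @param clamp truncate features into the training range (default TRUE)
#' @param outputScale output scale (default \code{"cloglog"})
#' @return a \linkS4class{SuitabilitySurface}; \code{provenance$clampingMask}
#'   is a logical matrix, TRUE where clamping occurred
#' @export
projectModel <- function(model, newStack, clamp = TRUE,
                         outputScale = "cloglog") {
  surf <- predictSurface(model, newStack, outputScale = outputScale,
                         clamp = clamp)
  cm <- matrix(FALSE, nrow(newStack@mask), ncol(newStack@mask))
  cm[surf@provenance$clampedCells] <- TRUE
  surf@provenance$clampingMask <- cm
  surf
}

#' Cell-wise mean of suitability surfaces
#'
#' Averages surfaces on identical grids and output scales (e.g. the
#' members of a future-climate scenario ensemble). A cell masked in any
#' input is masked in the output.
#'
#' @param surfaces list of SuitabilitySurface objects (>= 1)
#' @return a \linkS4class{SuitabilitySurface}
#' @export
averageSurfaces <- function(surfaces) {
  stopifnot(length(surfaces) >= 1L)
  ref <- surfaces[[1L]]
  for (s in surfaces[-1L]) {
    stopIfGridMismatch(ref, s, "surfaces")
    if (!identical(s@scale, ref@scale))
      stop("surfaces are on different output scales")
  }
  mask <- Reduce(`&`, lapply(surfaces, function(s) s@mask))
  acc <- Reduce(`+`, lapply(surfaces, function(s) {
    v <- s@values; v[!mask] <- 0; v
  })) / length(surfaces)
  acc[!mask] <- NA_real_
  out <- newSurface(acc, ref, ref@scale,
                    provenance = list(averagedOver = length(surfaces)))
  out@mask <- mask
  out
}

#' Training-presence suitability thresholds
#'
#' Extracts the surface values at the training presences and returns the
#' minimum training presence (marginal suitability) and the 5th and 10th
#' nearest-rank percentiles (moderate and high suitability): the value at
#' 1-based index \eqn{\lceil q n \rceil} of the ascending sorted values.
#'
#' @param surface a SuitabilitySurface
#' @param trainingPresences an OccurrenceSet (all on unmasked cells)
#' @return a \linkS4class{ThresholdSet} on the surface's output scale
#' @export
trainingThresholds <- function(surface, trainingPresences) {
  rec <- occRecords(trainingPresences)
  if (!nrow(rec)) stop("no training presences")
  cells <- cellFromXY(surface, rec$longitude, rec$latitude)
  if (anyNA(cells)) stop("presence outside the grid extent")
  off <- which(!surface@mask[cells])
  if (length(off))
    stop("presence on masked cell (rows ", paste(off, collapse = ", "), ")")
  v <- sort(surface@values[cells])
  n <- length(v)
  nearestRank <- function(q) v[max(1L, ceiling(q * n))]
  new("ThresholdSet", mtp = v[1L], p5 = nearestRank(0.05),
      p10 = nearestRank(0.10), scale = surface@scale)
}

#' Classify a surface into suitability categories
#'
#' Cells at or above the 10th percentile threshold are \code{high}; at or
#' above the 5th percentile, \code{moderate}; at or above the minimum
#' training presence, \code{marginal}; below it, \code{unsuitable}.
#' Lower bounds are inclusive.
#'
#' @param surface a SuitabilitySurface
#' @param thresholds a ThresholdSet on the same output scale
#' @return integer matrix of codes 0-3 (unsuitable, marginal, moderate,
#'   high), NA off-mask, with attribute \code{"levels"}
#' @export
classifySuitability <- function(surface, thresholds) {
  if (!identical(thresholds@scale, surface@scale))
    stop("thresholds are on a different output scale than the surface")
  v <- surface@values
  cls <- matrix(NA_integer_, nrow(v), ncol(v))
  idx <- which(surface@mask)
  x <- v[idx]
  cls[idx] <- (x >= thresholds@mtp) + (x >= thresholds@p5) +
    (x >= thresholds@p10)
  attr(cls, "levels") <- c("unsuitable", "marginal", "moderate", "high")
  cls
}

#' Per-category cell counts of a classified map
#'
#' @param classified output of \code{\link{classifySuitability}}
#' @return named integer vector over the four categories
#' @export
classAreas <- function(classified) {
  lv <- attr(classified, "levels")
  counts <- vapply(0:3, function(k)
    sum(classified == k, na.rm = TRUE), 0L)
  stats::setNames(counts, lv)
}

#' Relative favourability between two allelic surfaces
#'
#' Compares two suitability surfaces cell by cell; the allele with the
#' strictly greater value wins the cell. Exact ties go to the first
#' allele and are tallied. Percents are over unmasked cells shared by
#' both surfaces and always sum to 100.
#'
#' @param surfaceA,surfaceB SuitabilitySurface objects on the same grid
#'   and output scale
#' @param alleles character(2) labels (default taken from provenance or
#'   \code{c("A", "B")})
#' @return a \linkS4class{FavourabilityMap}
#' @export
relativeFavourability <- function(surfaceA, surfaceB,
                                  alleles = c("A", "B")) {
  stopIfGridMismatch(surfaceA, surfaceB, "surfaces")
  if (!identical(surfaceA@scale, surfaceB@scale))
    stop("surfaces are on different output scales")
  mask <- surfaceA@mask & surfaceB@mask
  idx <- which(mask)
  a <- surfaceA@values[idx]; b <- surfaceB@values[idx]
  win <- ifelse(a >= b, 1L, 2L)
  ties <- sum(a == b)
  w <- matrix(NA_integer_, nrow(mask), ncol(mask))
  w[idx] <- win
  pct <- c(sum(win == 1L), sum(win == 2L)) / length(idx) * 100
  new("FavourabilityMap", winner = w, alleles = alleles,
      percents = stats::setNames(pct, alleles), ties = as.integer(ties),
      provenance = list(scale = surfaceA@scale))
}
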