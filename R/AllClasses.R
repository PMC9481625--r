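#' @import methods
NULL

#' ClimateStack: co-registered gridded climate variables
#'
#' A stack of named climate layers on a common geographic grid (WGS84
#' lon/lat, cell-centre registered, row 1 = northernmost row), together
#' with a boolean study-area mask. A cell is in the mask iff it is
#' NoData-free in every layer.
#'
#' @slot layers numeric 3-d array \code{[nrow, ncol, nlayer]}; third
#'   dimension named by climate variable (e.g. \code{BIO10}). Off-mask
#'   cells are \code{NA}.
#' @slot mask logical matrix; \code{TRUE} marks study-area cells.
#' @slot xll,yll numeric; west/south edge of the lower-left cell (degrees).
#' @slot cellsize numeric; cell edge in degrees (square cells).
#' @slot nodata numeric; NoData sentinel used when writing to disk.
#' @aliases ClimateStack
#' @exportClass ClimateStack
setClass("ClimateStack",
  representation(
    layers   = "array",
    mask     = "matrix",
    xll      = "numeric",
    yll      = "numeric",
    cellsize = "numeric",
    nodata   = "numeric"
  )
)

setValidity("ClimateStack", function(object) {
  msg <- character()
  d <- dim(object@layers)
  if (length(d) != 3L) msg <- c(msg, "'layers' must be a 3-d array")
  else {
    if (is.null(dimnames(object@layers)[[3L]]))
      msg <- c(msg, "layers must be named along the third dimension")
    if (!identical(dim(object@mask), d[1:2]))
      msg <- c(msg, "mask dimensions must match layer dimensions")
    if (anyDuplicated(dimnames(object@layers)[[3L]]))
      msg <- c(msg, "duplicate layer names")
    # mask cells must be NoData-free in every layer
    if (length(d) == 3L && any(object@mask)) {
      idx <- which(object@mask)
      for (k in seq_len(d[3L])) {
        if (anyNA(object@layers[, , k][idx])) {
          msg <- c(msg, sprintf("mask cell is NA in layer '%s'",
                                dimnames(object@layers)[[3L]][k]))
          break
        }
      }
    }
  }
  if (object@cellsize <= 0) msg <- c(msg, "cellsize must be positive")
  if (length(msg)) msg else TRUE
})

#' OccurrenceSet: typed allele presence points
#'
#' @slot records data.frame with columns \code{longitude}, \code{latitude},
#'   \code{allele}. Duplicate (longitude, latitude, allele) triples are
#'   disallowed; a shared site may carry both allele labels as two records.
#' @slot provenance character note on origin.
#' @aliases OccurrenceSet
#' @exportClass OccurrenceSet
setClass("OccurrenceSet",
  representation(records = "data.frame", provenance = "character")
)

setValidity("OccurrenceSet", function(object) {
  msg <- character()
  r <- object@records
  need <- c("longitude", "latitude", "allele")
  if (!all(need %in% names(r)))
    return("records must have columns longitude, latitude, allele")
  if (nrow(r)) {
    if (any(abs(r$latitude) > 90))  msg <- c(msg, "|latitude| must be <= 90")
    if (any(abs(r$longitude) > 180)) msg <- c(msg, "|longitude| must be <= 180")
    if (anyDuplicated(r[need]))
      msg <- c(msg, "duplicate (longitude, latitude, allele) records")
  }
  if (length(msg)) msg else TRUE
})

#' FeatureExpansion is kept as a plain list inside MaxentModel:
#' classes, varNames, varMin, varMax, nHingeKnots, hingeKnots,
#' featureNames, featureClass, featureVar. Documented with buildFeatures().

#' MaxentModel: fitted maximum-entropy presence/background model
#'
#' @slot expansion list describing the feature expansion (classes used,
#'   per-variable training min/max for scaling and clamping, hinge knots,
#'   feature names/classes).
#' @slot lambda named numeric; one coefficient per feature.
#' @slot beta numeric; per-feature L1 weights used in the fit.
#' @slot Z numeric; background normalizer, sum over training background of
#'   \eqn{\exp(\lambda \cdot f)}.
#' @slot H numeric; entropy (nats) of the fitted distribution over the
#'   training background.
#' @slot meta list: nPresence, nBackground, regMultiplier, converged,
#'   objective, iterations, seed.
#' @aliases MaxentModel
#' @exportClass MaxentModel
setClass("MaxentModel",
  representation(
    expansion = "list",
    lambda    = "numeric",
    beta      = "numeric",
    Z         = "numeric",
    H         = "numeric",
    meta      = "list"
  )
)

setValidity("MaxentModel", function(object) {
  msg <- character()
  if (length(object@lambda) != length(object@beta))
    msg <- c(msg, "lambda and beta lengths differ")
  if (!(object@Z > 0)) msg <- c(msg, "Z must be positive")
  nb <- object@meta$nBackground
  if (!is.null(nb) && (object@H < -1e-9 || object@H > log(nb) + 1e-9))
    msg <- c(msg, "entropy H outside [0, ln(background size)]")
  if (length(msg)) msg else TRUE
})

#' SuitabilitySurface: per-cell suitability on a stack's grid
#'
#' @slot values numeric matrix on the grid; off-mask cells \code{NA}.
#' @slot scale one of \code{"raw"}, \code{"cumulative"}, \code{"cloglog"},
#'   or \code{"truth"} for generator ground truth.
#' @slot mask logical matrix (study area).
#' @slot xll,yll,cellsize grid registration as in \code{ClimateStack}.
#' @slot provenance list (model id, stack id, clamping flags...).
#' @aliases SuitabilitySurface
#' @exportClass SuitabilitySurface
setClass("SuitabilitySurface",
  representation(
    values     = "matrix",
    scale      = "character",
    mask       = "matrix",
    xll        = "numeric",
    yll        = "numeric",
    cellsize   = "numeric",
    provenance = "list"
  )
)

setValidity("SuitabilitySurface", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@mask)))
    msg <- c(msg, "values and mask dimensions differ")
  if (!object@scale %in% c("raw", "cumulative", "cloglog", "truth"))
    msg <- c(msg, "scale must be raw, cumulative, cloglog or truth")
  v <- object@values[object@mask]
  if (length(v) && anyNA(v)) msg <- c(msg, "NA value on a mask cell")
  if (object@scale %in% c("cumulative", "cloglog") && length(v) &&
      (min(v) < -1e-12 || max(v) > 1 + 1e-12))
    msg <- c(msg, sprintf("%s values must lie in [0,1]", object@scale))
  if (length(msg)) msg else TRUE
})

#' OverlapResult: observed Schoener's D with its permutation null
#'
#' @slot observedD numeric in [0,1].
#' @slot nullD numeric vector of null D values (length = n_reps).
#' @slot pValue numeric in (0,1]; add-one corrected permutation p-value.
#' @slot sided \code{"one-sided-lower"} or \code{"two-sided"}.
#' @slot space \code{"geographic"} or \code{"environmental"}.
#' @slot settings list snapshot of model settings used.
#' @slot seed integer seed that produced the null.
#' @aliases OverlapResult
#' @exportClass OverlapResult
setClass("OverlapResult",
  representation(
    observedD = "numeric",
    nullD     = "numeric",
    pValue    = "numeric",
    sided     = "character",
    space     = "character",
    settings  = "list",
    seed      = "integer"
  )
)

setValidity("OverlapResult", function(object) {
  msg <- character()
  if (object@observedD < -1e-12 || object@observedD > 1 + 1e-12)
    msg <- c(msg, "observed D outside [0,1]")
  if (!(object@pValue > 0 && object@pValue <= 1))
    msg <- c(msg, "p-value must lie in (0,1]")
  if (!object@sided %in% c("one-sided-lower", "two-sided"))
    msg <- c(msg, "unknown sidedness")
  if (!object@space %in% c("geographic", "environmental"))
    msg <- c(msg, "unknown overlap space")
  if (length(msg)) msg else TRUE
})

#' NicheTruth: ground-truth Gaussian climatic response of one allele
#'
#' The synthetic generator's truth: suitability is a product of Gaussian
#' responses, \eqn{s = \exp(-\sum_v (z_v-\mu_v)^2 / (2\sigma_v^2))}.
#'
#' @slot optimum named numeric; per-variable optimum (climate units).
#' @slot breadth named numeric; per-variable breadth, strictly positive.
#' @slot allele character allele label.
#' @aliases NicheTruth
#' @exportClass NicheTruth
setClass("NicheTruth",
  representation(optimum = "numeric", breadth = "numeric",
                 allele = "character")
)

setValidity("NicheTruth", function(object) {
  msg <- character()
  if (length(object@optimum) == 0L) msg <- c(msg, "empty variable subset")
  if (!identical(names(object@optimum), names(object@breadth)))
    msg <- c(msg, "optimum and breadth must share variable names")
  if (any(object@breadth <= 0)) msg <- c(msg, "breadth must be > 0")
  if (length(msg)) msg else TRUE
})

#' SyntheticWorld: a complete ground-truth testbed
#'
#' @slot present,future ClimateStack; \code{future} may have 0 layers
#'   (slot \code{hasFuture} FALSE) when no scenario shift is requested.
#' @slot hasFuture logical.
#' @slot truths named list of NicheTruth, one per allele.
#' @slot trueSurfaces named list of SuitabilitySurface (scale "truth").
#' @slot occurrences named list of OccurrenceSet, one per allele.
#' @slot seed integer RNG seed that generated the world.
#' @aliases SyntheticWorld
#' @exportClass SyntheticWorld
setClass("SyntheticWorld",
  representation(
    present      = "ClimateStack",
    future       = "ClimateStack",
    hasFuture    = "logical",
    truths       = "list",
    trueSurfaces = "list",
    occurrences  = "list",
    seed         = "integer"
  )
)

#' ThresholdSet: training-presence suitability thresholds
#'
#' @slot mtp minimum training presence (marginal suitability).
#' @slot p5 fifth percentile training presence (moderate suitability).
#' @slot p10 tenth percentile training presence (high suitability).
#' @slot scale output scale the thresholds live on.
#' @aliases ThresholdSet
#' @exportClass ThresholdSet
setClass("ThresholdSet",
  representation(mtp = "numeric", p5 = "numeric", p10 = "numeric",
                 scale = "character")
)

setValidity("ThresholdSet", function(object) {
  if (object@mtp > object@p5 + 1e-12 || object@p5 > object@p10 + 1e-12)
    "thresholds must satisfy mtp <= p5 <= p10" else TRUE
})

#' FavourabilityMap: per-cell winner between two allelic surfaces
#'
#' @slot winner integer matrix; 1 = first allele, 2 = second, NA off-mask.
#' @slot alleles character(2) allele labels.
#' @slot percents named numeric(2); percent of unmasked area won.
#' @slot ties integer; number of exact ties (assigned to the first allele).
#' @slot provenance list naming the surfaces compared.
#' @aliases FavourabilityMap
#' @exportClass FavourabilityMap
setClass("FavourabilityMap",
  representation(winner = "matrix", alleles = "character",
                 percents = "numeric", ties = "integer",
                 provenance = "list")
)

setValidity("FavourabilityMap", function(object) {
  msg <- character()
  if (length(object@alleles) != 2L) msg <- c(msg, "exactly two alleles")
  if (abs(sum(object@percents) - 100) > 1e-6)
    msg <- c(msg, "percents must sum to 100")
  if (length(msg)) msg else TRUE
})
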