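#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname layerNames
#' @export
setMethod("layerNames", "ClimateStack",
          function(x) dimnames(x@layers)[[3L]])

#' @rdname nLayers
#' @export
setMethod("nLayers", "ClimateStack", function(x) dim(x@layers)[3L])

#' @rdname gridDim
#' @export
setMethod("gridDim", "ClimateStack", function(x) dim(x@mask))

#' @rdname gridDim
#' @export
setMethod("gridDim", "SuitabilitySurface", function(x) dim(x@mask))

#' @rdname stackMask
#' @export
setMethod("stackMask", "ClimateStack", function(x) x@mask)

#' @rdname stackMask
#' @export
setMethod("stackMask", "SuitabilitySurface", function(x) x@mask)

#' @rdname surfaceValues
#' @export
setMethod("surfaceValues", "SuitabilitySurface", function(x, masked = FALSE) {
  if (masked) x@values[x@mask] else x@values
})

#' @rdname outputScale
#' @export
setMethod("outputScale", "SuitabilitySurface", function(x) x@scale)

#' @rdname occRecords
#' @export
setMethod("occRecords", "OccurrenceSet", function(x) x@records)

#' @rdname alleleCounts
#' @export
setMethod("alleleCounts", "OccurrenceSet", function(x) {
  tab <- table(x@records$allele)
  stats::setNames(as.integer(tab), names(tab))
})

#' @rdname observedD
#' @export
setMethod("observedD", "OverlapResult", function(x) x@observedD)

#' @rdname nullD
#' @export
setMethod("nullD", "OverlapResult", function(x) x@nullD)

#' @rdname pValue
#' @export
setMethod("pValue", "OverlapResult", function(x) x@pValue)

#' @rdname modelLambda
#' @export
setMethod("modelLambda", "MaxentModel", function(x) x@lambda)

#' @rdname modelEntropy
#' @export
setMethod("modelEntropy", "MaxentModel", function(x) x@H)

setMethod("show", "ClimateStack", function(object) {
  d <- gridDim(object)
  cat("ClimateStack:", d[1], "x", d[2], "cells,",
      nLayers(object), "layers\n")
  cat("  layers:", paste(layerNames(object), collapse = ", "), "\n")
  cat(sprintf("  origin (%.4f, %.4f), cellsize %.6f deg, %d mask cells\n",
              object@xll, object@yll, object@cellsize, sum(object@mask)))
})

setMethod("show", "OccurrenceSet", function(object) {
  cnt <- alleleCounts(object)
  cat("OccurrenceSet:", nrow(object@records), "records (",
      paste(sprintf("%s: %d", names(cnt), cnt), collapse = ", "), ")\n")
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "MaxentModel", function(object) {
  k <- sum(abs(object@lambda) > 0)
  cat("MaxentModel:", length(object@lambda), "features (",
      paste(object@expansion$classes, collapse = " + "), "),",
      k, "active\n")
  cat(sprintf("  n presence %d, background %d, reg multiplier %g\n",
              object@meta$nPresence, object@meta$nBackground,
              object@meta$regMultiplier))
  cat(sprintf("  entropy H = %.4f nats; converged: %s\n",
              object@H, object@meta$converged))
})

setMethod("show", "SuitabilitySurface", function(object) {
  v <- object@values[object@mask]
  cat(sprintf("SuitabilitySurface (%s): %d x %d grid, %d mask cells\n",
              object@scale, nrow(object@mask), ncol(object@mask),
              sum(object@mask)))
  if (length(v))
    cat(sprintf("  range [%.4g, %.4g]\n", min(v), max(v)))
})

setMethod("show", "OverlapResult", function(object) {
  cat(sprintf("OverlapResult (%s space): D = %.4f, p = %.4f (%s, %d reps)\n",
              object@space, object@observedD, object@pValue,
              object@sided, length(object@nullD)))
})

setMethod("show", "ThresholdSet", function(object) {
  cat(sprintf("ThresholdSet (%s): mtp %.4f <= p5 %.4f <= p10 %.4f\n",
              object@scale, object@mtp, object@p5, object@p10))
})

setMethod("show", "FavourabilityMap", function(object) {
  cat(sprintf("FavourabilityMap: %s %.1f%% vs %s %.1f%% (%d ties)\n",
              object@alleles[1], object@percents[1],
              object@alleles[2], object@percents[2], object@ties))
})

setMethod("show", "SyntheticWorld", function(object) {
  cat("SyntheticWorld: alleles",
      paste(names(object@truths), collapse = ", "),
      if (object@hasFuture) "(present + future stacks)"
      else "(present stack only)", "\n")
})
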