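#' @include AllClasses.R
NULL

#' Layer names of a gridded object
#' @param x a ClimateStack
#' @return character vector of layer (climate variable) names
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' Number of layers
#' @param x a ClimateStack
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' Grid dimension (rows, cols)
#' @param x a ClimateStack or SuitabilitySurface
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' Study-area mask
#' @param x a ClimateStack or SuitabilitySurface
#' @return logical matrix, TRUE on study-area cells
#' @export
setGeneric("stackMask", function(x) standardGeneric("stackMask"))

#' Per-cell values
#' @param x a SuitabilitySurface
#' @param masked if TRUE return only mask-cell values as a vector
#' @export
setGeneric("surfaceValues",
           function(x, masked = FALSE) standardGeneric("surfaceValues"))

#' Output scale of a surface
#' @param x a SuitabilitySurface
#' @export
setGeneric("outputScale", function(x) standardGeneric("outputScale"))

#' Occurrence records as a data.frame
#' @param x an OccurrenceSet
#' @export
setGeneric("occRecords", function(x) standardGeneric("occRecords"))

#' Per-allele record counts
#' @param x an OccurrenceSet
#' @return named integer vector of record counts per allele label
#' @export
setGeneric("alleleCounts", function(x) standardGeneric("alleleCounts"))

#' Observed Schoener's D of an overlap result
#' @param x an OverlapResult
#' @export
setGeneric("observedD", function(x) standardGeneric("observedD"))

#' Null distribution of an overlap result
#' @param x an OverlapResult
#' @export
setGeneric("nullD", function(x) standardGeneric("nullD"))

#' Permutation p-value of an overlap result
#' @param x an OverlapResult
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' Model coefficients (lambda)
#' @param x a MaxentModel
#' @export
setGeneric("modelLambda", function(x) standardGeneric("modelLambda"))

#' Model entropy (nats) over the training background
#' @param x a MaxentModel
#' @export
setGeneric("modelEntropy", function(x) standardGeneric("modelEntropy"))
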