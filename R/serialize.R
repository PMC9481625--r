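#' @include AllClasses.R
NULL

#' Write a fitted model as structured text (YAML)
#'
#' Stores the feature expansion, coefficients, regularization weights,
#' normalizer, entropy and training metadata; \code{\link{readMaxentModel}}
#' restores a model that predicts identically.
#'
#' @param model a MaxentModel
#' @param path output path
#' @export
writeMaxentModel <- function(model, path) {
  ex <- model@expansion
  yaml::write_yaml(list(
    expansion = list(
      classes = ex$classes, varNames = ex$varNames,
      varMin = as.list(ex$varMin), varMax = as.list(ex$varMax),
      nHingeKnots = ex$nHingeKnots,
      hingeKnots = as.numeric(ex$hingeKnots),
      featureNames = ex$featureNames),
    lambda = as.list(model@lambda),
    beta = as.numeric(model@beta),
    Z = model@Z, H = model@H,
    meta = model@meta[c("nPresence", "nBackground", "regMultiplier",
                        "converged", "iterations")]
  ), path, precision = 15)
  invisible(path)
}

#' Read a model written by \code{\link{writeMaxentModel}}
#'
#' @param path YAML path
#' @return a \linkS4class{MaxentModel}
#' @export
readMaxentModel <- function(path) {
  y <- yaml::read_yaml(path)
  ex <- y$expansion
  ex$varMin <- unlist(ex$varMin)
  ex$varMax <- unlist(ex$varMax)
  ex$hingeKnots <- as.numeric(ex$hingeKnots)
  new("MaxentModel", expansion = ex,
      lambda = unlist(y$lambda), beta = as.numeric(y$beta),
      Z = y$Z, H = y$H, meta = y$meta)
}
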