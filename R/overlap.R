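#' @include AllClasses.R maxent-predict.R extract.R utils.R
NULL

schoenerDFromVectors <- function(p, q) {
  sp <- sum(p); sq <- sum(q)
  if (sp <= 0 || sq <= 0) stop("zero total mass in a surface")
  1 - 0.5 * sum(abs(p / sp - q / sq))
}

#' Schoener's D between two suitability surfaces (geographic space)
#'
#' Each surface is normalized to sum to 1 over the shared unmasked cells;
#' \eqn{D = 1 - \frac12 \sum_i |p_i - q_i|}, from 0 (no overlap) to 1
#' (complete overlap). Symmetric, and invariant to multiplying either
#' surface by a positive constant.
#'
#' @param surfaceA,surfaceB non-negative SuitabilitySurface objects on
#'   the same grid
#' @return D in [0,1]
#' @export
schoenerD <- function(surfaceA, surfaceB) {
  stopIfGridMismatch(surfaceA, surfaceB, "surfaces")
  mask <- surfaceA@mask & surfaceB@mask
  a <- surfaceA@values[mask]; b <- surfaceB@values[mask]
  if (any(a < 0) || any(b < 0)) stop("surfaces must be non-negative")
  schoenerDFromVectors(a, b)
}

#' Schoener's D between two models in environmental space
#'
#' Draws a Latin-hypercube sample over the hyper-rectangle of the pooled
#' training ranges of both models, predicts both models there on the raw
#' scale (clamped), normalizes each score vector to sum to 1, and
#' computes D. Raw scores are used because D is computed on normalized
#' vectors, and only the raw scale is proportional to the Gibbs density.
#'
#' @param modelA,modelB MaxentModel objects carrying expansions
#' @param variableRanges optional named list of c(min, max) per variable;
#'   default: the union of both models' training ranges
#' @param nPoints Latin-hypercube sample size (>= 100; default 10000)
#' @param seed integer RNG seed
#' @return D in [0,1]
#' @export
schoenerDEnvironment <- function(modelA, modelB, variableRanges = NULL,
                                 nPoints = 10000, seed = 1) {
  if (nPoints < 100)
    stop("nPoints must be >= 100 for a stable estimate")
  vars <- union(modelA@expansion$varNames, modelB@expansion$varNames)
  if (is.null(variableRanges)) {
    variableRanges <- lapply(vars, function(v) {
      lo <- min(modelA@expansion$varMin[v], modelB@expansion$varMin[v],
                na.rm = TRUE)
      hi <- max(modelA@expansion$varMax[v], modelB@expansion$varMax[v],
                na.rm = TRUE)
      c(lo, hi)
    })
    names(variableRanges) <- vars
  }
  missing <- setdiff(vars, names(variableRanges))
  if (length(missing))
    stop("variableRanges does not cover: ", paste(missing, collapse = ", "))
  U <- withSeed(seed, lhs::randomLHS(nPoints, length(vars)))
  X <- vapply(seq_along(vars), function(j) {
    r <- variableRanges[[vars[j]]]
    r[1] + U[, j] * (r[2] - r[1])
  }, numeric(nPoints))
  colnames(X) <- vars
  a <- predictScores(modelA, X, outputScale = "raw", clamp = TRUE)
  b <- predictScores(modelB, X, outputScale = "raw", clamp = TRUE)
  schoenerDFromVectors(as.numeric(a), as.numeric(b))
}

## fit one allele's model from occurrences and a fixed background, then
## predict its raw surface over the stack's mask cells
fitAndRaw <- function(occ, stack, bgValues, settings, maskValues) {
  pres <- extractValues(stack, occ)
  fit <- fitFromValues(pres, bgValues, settings)
  as.numeric(predictScores(fit, maskValues, outputScale = "raw",
                           clamp = TRUE))
}

overlapSettings <- function(settings, nA) {
  settings$classes <- settings$classes %||% autoFeatureClasses(nA)
  settings
}

#' Niche identity (equivalency) test
#'
#' The observed D compares models fit to the two occurrence sets with
#' identical settings and a shared background. The null repartitions the
#' pooled occurrences at random into groups of the original sizes,
#' refits both models and recomputes D, \code{nReps} times. Because
#' truly divergent niches make the observed D *smaller* than nulls built
#' from scrambled labels, the p-value is one-sided-lower with add-one
#' correction: \eqn{p = (1 + \#\{D_{null} \le D_{obs}\})/(n_{reps}+1)}.
#'
#' @param occA,occB OccurrenceSet objects for the two alleles
#' @param stack the ClimateStack defining geography and background
#' @param modelSettings fit settings list (classes — default: auto from
#'   \code{|occA|} —, regMultiplier, nHingeKnots, tol, maxIter, kktTol,
#'   nBackground, default 1000)
#' @param nReps number of randomizations (>= 1; default 99)
#' @param seed integer RNG seed
#' @return an \linkS4class{OverlapResult} (geographic space)
#' @export
identityTest <- function(occA, occB, stack, modelSettings = list(),
                         nReps = 99, seed = 1) {
  stopifnot(nReps >= 1)
  recA <- occRecords(occA); recB <- occRecords(occB)
  settings <- overlapSettings(modelSettings, nrow(recA))
  bgN <- settings$nBackground %||% min(1000L, sum(stack@mask))
  bg <- sampleBackground(stack, bgN, seed = childSeed(seed, 777L))
  maskValues <- valuesAtCells(stack, which(stack@mask))
  rawOf <- function(presVals) {
    fit <- fitFromValues(presVals, bg$values, settings)
    as.numeric(predictScores(fit, maskValues, outputScale = "raw",
                             clamp = TRUE))
  }
  pooledVals <- rbind(extractValues(stack, occA),
                      extractValues(stack, occB))
  nA <- nrow(recA); nTot <- nrow(pooledVals)
  obsD <- schoenerDFromVectors(
    rawOf(pooledVals[seq_len(nA), , drop = FALSE]),
    rawOf(pooledVals[-seq_len(nA), , drop = FALSE]))
  nulls <- withSeed(seed, {
    vapply(seq_len(nReps), function(r) {
      for (attempt in 1:3) {
        idx <- sample.int(nTot, nA)
        d <- try(schoenerDFromVectors(
          rawOf(pooledVals[idx, , drop = FALSE]),
          rawOf(pooledVals[-idx, , drop = FALSE])), silent = TRUE)
        if (!inherits(d, "try-error")) return(d)
      }
      stop("identity test: replicate failed after 3 partition retries: ",
           attr(d, "condition")$message)
    }, 0)
  })
  p <- (1 + sum(nulls <= obsD)) / (nReps + 1)
  new("OverlapResult", observedD = obsD, nullD = nulls, pValue = p,
      sided = "one-sided-lower", space = "geographic",
      settings = settings, seed = as.integer(seed))
}

#' Background similarity test
#'
#' Asks whether the observed overlap differs from what identical
#' climatic tolerances would produce given the two regions' available
#' climates: the null replaces the second allele's occurrences with the
#' same number of points drawn uniformly from the unmasked cells of its
#' background region, refits, and recomputes D against the first
#' allele's observed model. The p-value is two-sided with add-one
#' correction, \eqn{p = \min(1, 2\min(P_{lower}, P_{upper}))}. Run the
#' symmetric direction by swapping the arguments.
#'
#' @param occA,occB OccurrenceSet objects; \code{occB} is randomized
#' @param stack the ClimateStack
#' @param backgroundRegionB logical matrix delimiting allele B's
#'   available region (default: the whole study mask)
#' @param modelSettings,nReps,seed as \code{\link{identityTest}}
#' @return an \linkS4class{OverlapResult} (geographic space)
#' @export
backgroundTest <- function(occA, occB, stack, backgroundRegionB = NULL,
                           modelSettings = list(), nReps = 99, seed = 1) {
  stopifnot(nReps >= 1)
  if (is.null(backgroundRegionB)) backgroundRegionB <- stack@mask
  stopifnot(identical(dim(backgroundRegionB), dim(stack@mask)))
  regionCells <- which(backgroundRegionB & stack@mask)
  nB <- nrow(occRecords(occB))
  if (length(regionCells) < nB)
    stop("background region has fewer unmasked cells than |occB|")
  settings <- overlapSettings(modelSettings, nrow(occRecords(occA)))
  bgN <- settings$nBackground %||% min(1000L, sum(stack@mask))
  bg <- sampleBackground(stack, bgN, seed = childSeed(seed, 778L))
  maskValues <- valuesAtCells(stack, which(stack@mask))
  rawOf <- function(occ) fitAndRaw(occ, stack, bg$values, settings,
                                   maskValues)
  rawA <- rawOf(occA)
  obsD <- schoenerDFromVectors(rawA, rawOf(occB))
  nulls <- withSeed(seed, {
    vapply(seq_len(nReps), function(r) {
      for (attempt in 1:3) {
        cells <- sample(regionCells, nB)
        d <- try({
          xy <- cellCentres(stack, cells)
          pb <- occurrenceSet(xy[, 1], xy[, 2],
                              rep("null-bg", nB),
                              provenance = "background draw")
          schoenerDFromVectors(rawA, rawOf(pb))
        }, silent = TRUE)
        if (!inherits(d, "try-error")) return(d)
      }
      stop("background test: replicate failed after 3 retries: ",
           attr(d, "condition")$message)
    }, 0)
  })
  pLower <- (1 + sum(nulls <= obsD)) / (nReps + 1)
  pUpper <- (1 + sum(nulls >= obsD)) / (nReps + 1)
  p <- min(1, 2 * min(pLower, pUpper))
  new("OverlapResult", observedD = obsD, nullD = nulls, pValue = p,
      sided = "two-sided", space = "geographic",
      settings = settings, seed = as.integer(seed))
}

#' Serialize an overlap result as YAML
#'
#' @param x an OverlapResult
#' @param path output path
#' @export
writeOverlapResult <- function(x, path) {
  yaml::write_yaml(list(
    observedD = x@observedD, nullD = as.numeric(x@nullD),
    pValue = x@pValue, sided = x@sided, space = x@space,
    settings = x@settings[!vapply(x@settings, is.function, TRUE)],
    seed = x@seed), path, precision = 15)
  invisible(path)
}
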