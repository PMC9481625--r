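#' @include AllClasses.R maxent-fit.R maxent-predict.R extract.R utils.R
NULL

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The fraction of (presence, background) score pairs in which the
#' presence scores higher, ties counting one half. Invariant under any
#' strictly increasing transform of the scores.
#'
#' @param presenceScores,backgroundScores non-empty numeric vectors
#' @return AUC in [0,1]
#' @export
aucScore <- function(presenceScores, backgroundScores) {
  if (!length(presenceScores) || !length(backgroundScores))
    stop("both score vectors must be non-empty")
  m <- length(presenceScores); n <- length(backgroundScores)
  r <- rank(c(presenceScores, backgroundScores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

## ROC vertices (fpr, tpr) for thresholds decreasing over unique scores
rocCurve <- function(pres, bg) {
  th <- sort(unique(c(pres, bg)), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(pres >= t), 0)
  fpr <- vapply(th, function(t) mean(bg >= t), 0)
  list(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}

## Partial area ratio restricted to sensitivity >= 1 - E:
## model area = trapezoid integral of tpr over fpr on that region (the
## entry point at tpr = 1-E is linearly interpolated); null area = the
## diagonal's integral over the same fpr range.
pAucRatioOnce <- function(pres, bg, E) {
  rc <- rocCurve(pres, bg)
  s0 <- 1 - E
  i <- which(rc$tpr >= s0)[1L]
  if (i == 1L) { f0 <- 0; t0 <- rc$tpr[1L] }
  else {
    # interpolate along the segment crossing tpr = 1 - E
    t1 <- rc$tpr[i - 1L]; t2 <- rc$tpr[i]
    f1 <- rc$fpr[i - 1L]; f2 <- rc$fpr[i]
    w <- if (t2 > t1) (s0 - t1) / (t2 - t1) else 1
    f0 <- f1 + w * (f2 - f1); t0 <- s0
  }
  fs <- c(f0, rc$fpr[i:length(rc$fpr)])
  ts <- c(t0, rc$tpr[i:length(rc$tpr)])
  modelArea <- sum(diff(fs) * (utils::head(ts, -1) + utils::tail(ts, -1)) / 2)
  nullArea <- (1 - f0^2) / 2
  if (nullArea <= 0) return(NA_real_)
  modelArea / nullArea
}

#' Partial-AUC ratio with presence bootstrap
#'
#' Per bootstrap replicate, a fraction of the presences is resampled with
#' replacement; the ROC against the full background is restricted to the
#' high-sensitivity region (sensitivity >= 1 - omission E) and the model's
#' partial area is divided by the chance diagonal's partial area over the
#' same region. Ratios above 1 indicate better-than-chance prediction;
#' the reported p-value is the proportion of replicates with ratio <= 1.
#'
#' @param presenceScores,backgroundScores numeric score vectors
#' @param omissionE allowed omission, in (0, 0.5) (default 0.05)
#' @param nBoot bootstrap replicates (default 100)
#' @param resampleFraction fraction of presences resampled per replicate
#'   (default 0.5)
#' @param seed integer RNG seed
#' @return list: \code{meanRatio}, \code{pValue}, \code{ratios}
#' @export
partialAucRatio <- function(presenceScores, backgroundScores,
                            omissionE = 0.05, nBoot = 100,
                            resampleFraction = 0.5, seed = 1) {
  if (!(omissionE > 0 && omissionE < 0.5))
    stop("omissionE must lie in (0, 0.5)")
  m <- length(presenceScores)
  k <- max(1L, round(resampleFraction * m))
  if (m < 2L) stop("too few presences to resample")
  ratios <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      pAucRatioOnce(presenceScores[sample.int(m, k, replace = TRUE)],
                    backgroundScores, omissionE)
    }, 0)
  })
  ratios <- ratios[!is.na(ratios)]
  list(meanRatio = mean(ratios), pValue = mean(ratios <= 1),
       ratios = ratios)
}

#' Random train/test splits for subsampling replicates
#'
#' Each replicate draws \code{round(testFraction * n)} distinct test
#' indices uniformly; replicates are independent and reproducible from
#' the seed.
#'
#' @param nPoints number of records to split
#' @param nReplicates number of replicates
#' @param testFraction fraction withheld for testing, in (0, 1)
#'   (default 0.25)
#' @param seed integer RNG seed
#' @return list with \code{splits} (per replicate: \code{train},
#'   \code{test} index vectors), \code{nReplicates}, \code{testFraction},
#'   \code{seed}
#' @export
subsampleReplicates <- function(nPoints, nReplicates, testFraction = 0.25,
                                seed = 1) {
  if (!(testFraction > 0 && testFraction < 1))
    stop("testFraction must lie in (0, 1)")
  k <- round(testFraction * nPoints)
  if (k < 1L || k >= nPoints)
    stop("impossible split sizes: test size ", k, " of ", nPoints)
  splits <- withSeed(seed, {
    lapply(seq_len(nReplicates), function(r) {
      test <- sort(sample.int(nPoints, k))
      list(train = setdiff(seq_len(nPoints), test), test = test)
    })
  })
  list(splits = splits, nReplicates = nReplicates,
       testFraction = testFraction, seed = as.integer(seed))
}

## shared settings plumbing for fits driven from raw climate values
fitFromValues <- function(presValues, bgValues, settings) {
  trainMaxent(presValues, bgValues,
              classes = settings$classes,
              nHingeKnots = settings$nHingeKnots %||% 8,
              regMultiplier = settings$regMultiplier %||% 1,
              tol = settings$tol %||% 1e-5,
              maxIter = settings$maxIter %||% 500,
              kktTol = settings$kktTol %||% 1e-7)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Jackknife variable importance
#'
#' For every variable, fits a model on that variable alone and a model on
#' all variables except it, reporting the unregularized training gain of
#' each (\code{\link{trainingGain}}).
#'
#' @param presenceValues,backgroundValues raw climate-value matrices with
#'   named columns (>= 2 variables)
#' @param settings list of fit settings: \code{classes} (NULL = auto),
#'   \code{regMultiplier}, \code{nHingeKnots}, \code{tol}, \code{maxIter},
#'   \code{kktTol}
#' @return data.frame with columns \code{variable}, \code{gainAlone},
#'   \code{gainWithout}; attribute \code{"fullGain"} carries the
#'   all-variable model's gain
#' @export
jackknifeImportance <- function(presenceValues, backgroundValues,
                                settings = list()) {
  P <- as.matrix(presenceValues); B <- as.matrix(backgroundValues)
  vars <- colnames(P)
  if (length(vars) < 2L) stop("need at least 2 variables")
  gainOf <- function(cols) {
    fit <- tryCatch(
      fitFromValues(P[, cols, drop = FALSE], B[, cols, drop = FALSE],
                    settings),
      error = function(e) stop("fit failed for variables [",
                               paste(cols, collapse = ", "), "]: ",
                               conditionMessage(e), call. = FALSE))
    Fp <- applyFeatures(fit@expansion, P[, cols, drop = FALSE],
                        clamp = FALSE)
    Fb <- applyFeatures(fit@expansion, B[, cols, drop = FALSE],
                        clamp = FALSE)
    trainingGain(fit, Fp, Fb)
  }
  alone <- vapply(vars, function(v) gainOf(v), 0)
  without <- vapply(vars, function(v) gainOf(setdiff(vars, v)), 0)
  out <- data.frame(variable = vars, gainAlone = unname(alone),
                    gainWithout = unname(without))
  attr(out, "fullGain") <- gainOf(vars)
  out
}

#' Reiterative jackknife variable selection with correlation filter
#'
#' Starting from all stack variables, repeatedly fits models and drops
#' the variable with the lowest stand-alone gain until \code{targetK}
#' remain; then enforces the collinearity filter on background-cell
#' values: while any pair of surviving variables has |Pearson r| above
#' \code{rThreshold}, the member with the lower stand-alone gain is
#' dropped. Every step is recorded.
#'
#' @param stack a ClimateStack
#' @param trainingOccurrences an OccurrenceSet used as training presences
#' @param rThreshold correlation filter threshold in (0, 1] (default 0.8)
#' @param targetK number of variables to keep before the filter
#'   (default 4)
#' @param settings fit settings (see \code{\link{jackknifeImportance}});
#'   \code{nBackground} (default 1000) controls the background sample
#' @param seed integer RNG seed for the background sample
#' @return list: \code{finalVariables}, \code{steps} (per-iteration
#'   jackknife tables), \code{removed} (in drop order),
#'   \code{correlation} (matrix over background cells on the final set),
#'   \code{background} (sampled cells)
#' @export
selectVariables <- function(stack, trainingOccurrences, rThreshold = 0.8,
                            targetK = 4, settings = list(), seed = 1) {
  if (targetK < 1L) stop("targetK must be >= 1")
  if (!(rThreshold > 0 && rThreshold <= 1))
    stop("rThreshold must lie in (0, 1]")
  if (nLayers(stack) < targetK)
    stop("stack has fewer variables than targetK")
  bgN <- settings$nBackground %||% min(1000L, sum(stack@mask))
  bg <- sampleBackground(stack, bgN, seed = seed)
  P <- extractValues(stack, trainingOccurrences)
  vars <- layerNames(stack)
  steps <- list(); removed <- character()
  lastTable <- NULL
  while (length(vars) > targetK) {
    jk <- jackknifeImportance(P[, vars, drop = FALSE],
                              bg$values[, vars, drop = FALSE], settings)
    drop <- jk$variable[which.min(jk$gainAlone)]
    steps[[length(steps) + 1L]] <- jk
    removed <- c(removed, drop)
    vars <- setdiff(vars, drop)
    lastTable <- jk
  }
  ## stand-alone gains of the surviving set, for filter tie-breaking
  gainAlone <- if (!is.null(lastTable))
    stats::setNames(lastTable$gainAlone, lastTable$variable)[vars]
  else {
    jk <- jackknifeImportance(P[, vars, drop = FALSE],
                              bg$values[, vars, drop = FALSE], settings)
    steps[[length(steps) + 1L]] <- jk
    stats::setNames(jk$gainAlone, jk$variable)[vars]
  }
  repeat {
    cm <- stats::cor(bg$values[, vars, drop = FALSE])
    diag(cm) <- 0
    worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1L, ]
    if (max(abs(cm)) <= rThreshold) break
    pair <- vars[worst]
    drop <- pair[which.min(gainAlone[pair])]
    removed <- c(removed, drop)
    vars <- setdiff(vars, drop)
    if (length(vars) == 1L) break
  }
  finalCor <- stats::cor(bg$values[, vars, drop = FALSE])
  list(finalVariables = vars, steps = steps, removed = removed,
       correlation = finalCor, background = bg)
}
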