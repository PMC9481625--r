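#' @include AllClasses.R features.R maxent-fit.R grid-geometry.R extract.R
NULL

#' Per-row MaxEnt scores on an output scale
#'
#' \itemize{
#'   \item \code{raw}: \eqn{\exp(\lambda f(x))} normalized to sum to 1
#'     over the supplied rows (the prediction domain).
#'   \item \code{cumulative}: for each row, the summed raw mass of all
#'     rows with raw value \eqn{\le} its own (in [0,1]).
#'   \item \code{cloglog}: \eqn{1 - \exp(-e^{H} \cdot raw_{train}(x))}
#'     with \eqn{H} the entropy of the fitted distribution over the
#'     training background and \eqn{raw_{train}} the raw score
#'     re-normalized to the training background (divided by the stored
#'     normalizer Z), so the transform does not depend on the size of the
#'     prediction domain. The uniform model gives \eqn{1 - e^{-1}}
#'     everywhere.
#' }
#'
#' @param model a MaxentModel carrying a feature expansion
#' @param values climate-value matrix (rows = prediction points); or an
#'   already-expanded feature matrix when \code{isFeatures = TRUE}
#' @param outputScale \code{"raw"}, \code{"cumulative"} or \code{"cloglog"}
#' @param clamp truncate scaled features into the training range
#' @param isFeatures set TRUE if \code{values} are feature columns already
#' @return numeric scores; attribute \code{"clamped"} marks rows whose
#'   raw values left the training range
#' @export
predictScores <- function(model, values, outputScale = "cloglog",
                          clamp = TRUE, isFeatures = FALSE) {
  outputScale <- match.arg(outputScale, c("raw", "cumulative", "cloglog"))
  if (isFeatures) {
    Fm <- as.matrix(values)
    clamped <- rep(FALSE, nrow(Fm))
  } else {
    if (!length(model@expansion))
      stop("model carries no feature expansion; pass features directly")
    Fm <- applyFeatures(model@expansion, values, clamp = clamp)
    clamped <- attr(Fm, "clamped")
  }
  eta <- as.numeric(Fm %*% model@lambda)
  M <- max(eta)
  e <- exp(eta - M)
  out <- switch(outputScale,
    raw = e / sum(e),
    cumulative = {
      raw <- e / sum(e)
      ord <- order(raw)
      cum <- cumsum(raw[ord])
      # rows tied on raw share the mass of all rows <= their value
      tiedMax <- stats::ave(cum, raw[ord], FUN = max)
      res <- numeric(length(raw))
      res[ord] <- tiedMax
      res
    },
    cloglog = 1 - exp(-exp(model@H) * exp(eta) / model@Z)
  )
  attr(out, "clamped") <- clamped
  out
}

#' Predict a suitability surface over a climate stack
#'
#' @param object a MaxentModel
#' @param stack a ClimateStack carrying all model variables
#' @param outputScale,clamp see \code{\link{predictScores}}
#' @return a \linkS4class{SuitabilitySurface}; provenance records the
#'   scale, clamp flag and the indices of clamped cells
#' @export
predictSurface <- function(object, stack, outputScale = "cloglog",
                           clamp = TRUE) {
  cells <- which(stack@mask)
  vals <- valuesAtCells(stack, cells)
  sc <- predictScores(object, vals, outputScale = outputScale,
                      clamp = clamp)
  v <- matrix(NA_real_, nrow(stack@mask), ncol(stack@mask))
  v[cells] <- as.numeric(sc)
  newSurface(v, stack, outputScale,
             provenance = list(scale = outputScale, clamp = clamp,
                               clampedCells = cells[attr(sc, "clamped")]))
}

#' @describeIn predictSurface \code{predict} method: dispatches to
#'   \code{predictSurface} for a ClimateStack and to
#'   \code{predictScores} for a matrix of climate values.
#' @param newdata ClimateStack or climate-value matrix
#' @param ... passed through (\code{outputScale}, \code{clamp})
#' @export
setMethod("predict", "MaxentModel", function(object, newdata, ...) {
  if (is(newdata, "ClimateStack")) predictSurface(object, newdata, ...)
  else predictScores(object, newdata, ...)
})

#' Small-sample-corrected AIC of a MaxEnt model
#'
#' The likelihood is the landscape-normalized raw score at the presences:
#' \eqn{\ln L = \sum_i \ln raw(x_i)} with raw summing to 1 over the full
#' landscape; \eqn{K} counts nonzero coefficients;
#' \eqn{AICc = 2K - 2\ln L + 2K(K+1)/(n-K-1)}. Candidates with
#' \eqn{n \le K+1} are invalid (undefined correction) and excluded from
#' tuning.
#'
#' @param model a MaxentModel
#' @param presenceFeatures feature matrix at the presences
#' @param landscapeFeatures feature matrix over the full landscape
#'   (typically every unmasked cell)
#' @return list with \code{aicc}, \code{lnL}, \code{K}, \code{n},
#'   \code{valid}
#' @export
aicc <- function(model, presenceFeatures, landscapeFeatures) {
  P <- as.matrix(presenceFeatures); L <- as.matrix(landscapeFeatures)
  n <- nrow(P)
  if (n == 0L) stop("zero presences")
  lam <- model@lambda
  etaL <- as.numeric(L %*% lam)
  M <- max(etaL)
  logZ <- M + log(sum(exp(etaL - M)))
  lnL <- sum(as.numeric(P %*% lam) - logZ)
  K <- sum(abs(lam) > 0)
  if (n <= K + 1L)
    return(list(aicc = NA_real_, lnL = lnL, K = K, n = n, valid = FALSE))
  list(aicc = 2 * K - 2 * lnL + 2 * K * (K + 1) / (n - K - 1),
       lnL = lnL, K = K, n = n, valid = TRUE)
}

#' Tune feature classes and regularization multiplier by AICc
#'
#' Fits every combination of candidate feature-class sets and
#' regularization multipliers and scores each by \code{\link{aicc}} over
#' the landscape. The winner has the lowest AICc; ties break by fewer
#' nonzero coefficients, then by lower multiplier.
#'
#' @param presenceValues,backgroundValues raw climate-value matrices
#' @param featureSets list of candidate class sets (compact codes OK),
#'   e.g. \code{list("L", "LQ", "LQH")}
#' @param multipliers candidate regularization multipliers
#'   (default \code{c(0.5, 1, 2, 4)})
#' @param landscapeValues climate values over the full landscape for the
#'   AICc likelihood (default: the background values)
#' @param nHingeKnots,tol,maxIter,kktTol passed to the fits
#' @return list: \code{best} (fitted MaxentModel), \code{classes},
#'   \code{multiplier}, and \code{table} (per-candidate AICc data.frame)
#' @export
tuneMaxent <- function(presenceValues, backgroundValues,
                       featureSets = list("L", "LQ", "LQH"),
                       multipliers = c(0.5, 1, 2, 4),
                       landscapeValues = backgroundValues,
                       nHingeKnots = 8, tol = 1e-5, maxIter = 500,
                       kktTol = 1e-7) {
  presenceValues <- as.matrix(presenceValues)
  rows <- list(); fits <- list()
  for (fs in featureSets) for (mu in multipliers) {
    code <- paste(substr(toupper(parseClasses(fs)), 1, 1), collapse = "")
    code <- gsub("Q", "Q", code)
    fit <- try(trainMaxent(presenceValues, backgroundValues, classes = fs,
                           nHingeKnots = nHingeKnots,
                           regMultiplier = mu, tol = tol,
                           maxIter = maxIter, kktTol = kktTol),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      rows[[length(rows) + 1L]] <-
        data.frame(classes = code, multiplier = mu, K = NA, lnL = NA,
                   aicc = NA, valid = FALSE)
      next
    }
    Fp <- applyFeatures(fit@expansion, presenceValues, clamp = FALSE)
    Fl <- applyFeatures(fit@expansion, as.matrix(landscapeValues),
                        clamp = TRUE)
    sc <- aicc(fit, Fp, Fl)
    fits[[length(rows) + 1L]] <- fit
    rows[[length(rows) + 1L]] <-
      data.frame(classes = code, multiplier = mu, K = sc$K, lnL = sc$lnL,
                 aicc = ifelse(sc$valid, sc$aicc, NA), valid = sc$valid)
  }
  tab <- do.call(rbind, rows)
  ok <- which(tab$valid)
  if (!length(ok)) stop("all tuning candidates invalid (n <= K + 1)")
  ord <- ok[order(tab$aicc[ok], tab$K[ok], tab$multiplier[ok])]
  best <- ord[1L]
  list(best = fits[[best]], classes = tab$classes[best],
       multiplier = tab$multiplier[best], table = tab)
}
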