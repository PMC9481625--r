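#' @include AllClasses.R features.R
NULL

## Published MaxEnt default regularization weights by feature class,
## interpolated on the presence count (linear/quadratic/product share one
## table; hinge is constant 0.5).
LQP_REG_TABLE <- list(m = c(0, 10, 30, 100), w = c(1, 1, 0.2, 0.05))

classRegWeight <- function(featureClass, nPresence) {
  lqp <- stats::approx(LQP_REG_TABLE$m, LQP_REG_TABLE$w,
                       xout = min(nPresence, 100), rule = 2)$y
  ifelse(featureClass == "hinge", 0.5, lqp)
}

#' Per-feature L1 weights for a MaxEnt fit
#'
#' \eqn{\beta_j = mult \times w_{class}(m) \times s_j / \sqrt{m}} with
#' \eqn{s_j} the feature's standard deviation over the presences and
#' \eqn{w_{class}} the published per-class default weight.
#'
#' @param presenceFeatures presence feature matrix
#' @param featureClasses character vector, class of each column
#' @param regMultiplier global regularization multiplier
#' @return numeric vector of weights, one per feature
#' @export
regularizationWeights <- function(presenceFeatures, featureClasses,
                                  regMultiplier = 1) {
  m <- nrow(presenceFeatures)
  s <- apply(presenceFeatures, 2L, stats::sd)
  regMultiplier * classRegWeight(featureClasses, m) * s / sqrt(m)
}

#' Fit a maximum-entropy presence/background model
#'
#' Minimizes the L1-regularized negative mean presence log-likelihood of
#' the Gibbs distribution \eqn{q_\lambda(x) = \exp(\lambda f(x))/Z} over
#' the background:
#' \deqn{obj(\lambda) = -\frac1m\sum_i \lambda f(x_i) + \ln Z(\lambda)
#'   + \sum_j \beta_j |\lambda_j|}
#' by cyclic coordinate descent with soft-thresholding; each coordinate
#' step carries a 1-d backtracking guard so the objective sequence is
#' non-increasing. Iteration stops when the KKT stationarity conditions
#' hold to \code{kktTol} (so every feature satisfies
#' \eqn{|empirical\ mean_j - model\ mean_j| \le \beta_j + kktTol}) or
#' when the per-cycle objective improvement falls below \code{tol} with
#' stationarity already within \code{tol}.
#'
#' @param presenceFeatures m x p presence feature matrix (m >= 2)
#' @param backgroundFeatures n x p background feature matrix (n > m)
#' @param regMultiplier global regularization multiplier (default 1)
#' @param tol objective-improvement tolerance (default 1e-5)
#' @param maxIter maximum coordinate-descent cycles (default 500)
#' @param kktTol stationarity tolerance (default 1e-7)
#' @param beta optional explicit per-feature L1 weights; default computed
#'   by \code{\link{regularizationWeights}} using \code{featureClasses}
#' @param featureClasses per-column class labels (needed when beta is
#'   computed); default all \code{"linear"}
#' @param expansion optional feature expansion to store in the model
#' @return a \linkS4class{MaxentModel}; \code{meta(model)$converged} is
#'   FALSE (with a warning) when \code{maxIter} is exhausted
#' @export
fitMaxent <- function(presenceFeatures, backgroundFeatures,
                      regMultiplier = 1, tol = 1e-5, maxIter = 500,
                      kktTol = 1e-7, beta = NULL, featureClasses = NULL,
                      expansion = list()) {
  P <- as.matrix(presenceFeatures); B <- as.matrix(backgroundFeatures)
  m <- nrow(P); n <- nrow(B)
  if (m < 2L) stop("need at least 2 presences")
  if (n <= m) stop("background must be strictly larger than presence set")
  if (ncol(P) != ncol(B)) stop("feature dimension mismatch")
  p <- ncol(P)
  if (is.null(featureClasses)) featureClasses <- rep("linear", p)
  if (is.null(beta))
    beta <- regularizationWeights(P, featureClasses, regMultiplier)
  beta <- pmax(rep_len(beta, p), 0)
  empMean <- colMeans(P)
  lambda <- numeric(p)
  eta <- numeric(n)

  objective <- function(eta, lambda) {
    M <- max(eta)
    -sum(lambda * empMean) + M + log(sum(exp(eta - M))) +
      sum(beta * abs(lambda))
  }

  obj <- objective(eta, lambda)   # = log(n) at lambda = 0
  objTrace <- obj
  converged <- FALSE
  iter <- 0L
  kkt <- Inf
  repeat {
    iter <- iter + 1L
    objPrev <- obj
    for (j in seq_len(p)) {
      M <- max(eta); w <- exp(eta - M); sw <- sum(w)
      bj <- B[, j]
      mj <- sum(w * bj) / sw
      vj <- max(sum(w * bj * bj) / sw - mj * mj, 1e-8)
      g <- mj - empMean[j]
      u <- lambda[j] * vj - g
      lnew <- sign(u) * max(abs(u) - beta[j], 0) / vj
      delta <- lnew - lambda[j]
      if (abs(delta) < 1e-14) next
      if (abs(delta) > 10) delta <- sign(delta) * 10
      # 1-d backtracking: guarantee the objective does not increase
      for (bt in 1:40) {
        cand <- lambda[j] + delta
        dObj <- -delta * empMean[j] +
          log(sum(w * exp(delta * bj)) / sw) +
          beta[j] * (abs(cand) - abs(lambda[j]))
        if (dObj <= 1e-12) break
        delta <- delta / 2
      }
      if (dObj > 1e-12) next
      lambda[j] <- lambda[j] + delta
      eta <- eta + delta * bj
      obj <- obj + dObj
    }
    ## stationarity check on fresh model means
    M <- max(eta); w <- exp(eta - M); w <- w / sum(w)
    modelMean <- as.numeric(crossprod(B, w))
    grad <- modelMean - empMean
    viol <- ifelse(lambda != 0,
                   abs(grad + beta * sign(lambda)),
                   pmax(abs(grad) - beta, 0))
    kkt <- max(viol)
    obj <- objective(eta, lambda)
    objTrace <- c(objTrace, obj)
    if (kkt <= kktTol) { converged <- TRUE; break }
    if (objPrev - obj < tol && kkt <= tol) {
      converged <- TRUE; break
    }
    if (iter >= maxIter) break
  }
  if (!converged)
    warning(sprintf(
      "coordinate descent not converged after %d cycles (KKT gap %.2e)",
      iter, kkt))
  M <- max(eta); wq <- exp(eta - M); Z <- sum(wq) * exp(M)
  q <- wq / sum(wq)
  H <- -sum(ifelse(q > 0, q * log(q), 0))
  nm <- colnames(P)
  if (is.null(nm)) nm <- paste0("f", seq_len(p))
  names(lambda) <- nm
  new("MaxentModel", expansion = expansion, lambda = lambda, beta = beta,
      Z = Z, H = H,
      meta = list(nPresence = m, nBackground = n,
                  regMultiplier = regMultiplier, converged = converged,
                  objective = obj, objTrace = objTrace,
                  iterations = iter, kkt = kkt,
                  featureClasses = featureClasses))
}

#' Train a MaxEnt model from raw climate values
#'
#' Convenience wrapper: builds the feature expansion from the pooled
#' training values (presences + background, so the training range covers
#' both), then fits. Feature classes default to the presence-count auto
#' rule (\code{\link{autoFeatureClasses}}).
#'
#' @param presenceValues m x p matrix of climate values at presences
#' @param backgroundValues n x p matrix at background cells
#' @param classes feature classes (\code{NULL} = auto by presence count)
#' @param nHingeKnots hinge knots per variable
#' @param regMultiplier,tol,maxIter,kktTol passed to \code{\link{fitMaxent}}
#' @return a \linkS4class{MaxentModel} carrying its expansion
#' @export
trainMaxent <- function(presenceValues, backgroundValues, classes = NULL,
                        nHingeKnots = 8, regMultiplier = 1, tol = 1e-5,
                        maxIter = 500, kktTol = 1e-7) {
  presenceValues <- as.matrix(presenceValues)
  backgroundValues <- as.matrix(backgroundValues)
  if (nrow(unique(presenceValues)) == 1L)
    stop("degenerate presence set: all presence records identical")
  if (is.null(classes)) classes <- autoFeatureClasses(nrow(presenceValues))
  fb <- buildFeatures(rbind(presenceValues, backgroundValues),
                      classes = classes, nHingeKnots = nHingeKnots)
  m <- nrow(presenceValues)
  fitMaxent(fb$features[seq_len(m), , drop = FALSE],
            fb$features[-seq_len(m), , drop = FALSE],
            regMultiplier = regMultiplier, tol = tol, maxIter = maxIter,
            kktTol = kktTol,
            featureClasses = featureColumnClasses(fb$expansion),
            expansion = fb$expansion)
}

#' Unregularized training gain of a fitted model
#'
#' \eqn{gain = \ln(n_{bg}) - [-\frac1m\sum_i \lambda f(x_i) + \ln Z]};
#' zero for the uniform model, larger for models that concentrate mass on
#' the presences.
#'
#' @param model a MaxentModel
#' @param presenceFeatures,backgroundFeatures the training feature
#'   matrices
#' @return gain in nats
#' @export
trainingGain <- function(model, presenceFeatures, backgroundFeatures) {
  lam <- model@lambda
  etaP <- as.numeric(as.matrix(presenceFeatures) %*% lam)
  etaB <- as.numeric(as.matrix(backgroundFeatures) %*% lam)
  M <- max(etaB)
  nll <- -mean(etaP) + M + log(sum(exp(etaB - M)))
  log(nrow(as.matrix(backgroundFeatures))) - nll
}
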