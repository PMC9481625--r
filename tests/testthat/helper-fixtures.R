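# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), .fixtures)
  get(name, envir = .fixtures)
}

# Small divergent-niche world: cold allele (low ENV1 optimum) vs warm
# allele (high ENV1 optimum), with a +2 sd warming shift on ENV1.
divergentWorld <- function() fixture("divergent", function() {
  makeSyntheticWorld(nRows = 60, nCols = 60, nVars = 4,
                     smoothingScale = 3, interVarCorrelation = 0.3,
                     nOcc = c(HbS = 40, HbF = 57),
                     futureShift = c(ENV1 = 2), seed = 42)
})

# Exchangeable-null world: both alleles drawn from one shared niche.
sharedNicheWorld <- function(seed) {
  shared <- list(
    HbS = nicheTruth(c(ENV1 = 0, ENV2 = 0), 1.2, "HbS"),
    HbF = nicheTruth(c(ENV1 = 0, ENV2 = 0), 1.2, "HbF"))
  makeSyntheticWorld(nRows = 60, nCols = 60, nVars = 2,
                     smoothingScale = 3, interVarCorrelation = 0,
                     nOcc = c(HbS = 40, HbF = 57), truths = shared,
                     futureShift = NULL, seed = seed)
}

# A tiny hand-made 3x3 stack with known values.
tinyStack <- function(naCell = FALSE) {
  a <- matrix(as.numeric(1:9), 3, 3, byrow = TRUE)
  b <- matrix(as.numeric(9:1), 3, 3, byrow = TRUE)
  if (naCell) b[2, 2] <- NA
  climateStack(list(V1 = a, V2 = b), xll = 0, yll = 0, cellsize = 1)
}

# Feature matrices for a small seeded presence/background problem.
smallFitProblem <- function(seed = 7, m = 30, n = 300, informative = TRUE) {
  set.seed(seed)
  bgx <- stats::rnorm(n)
  px <- if (informative) stats::rnorm(m, 1, 0.5) else stats::rnorm(m)
  vals <- rbind(matrix(px, ncol = 1), matrix(bgx, ncol = 1))
  colnames(vals) <- "x"
  fb <- buildFeatures(vals, "LQ")
  list(P = fb$features[seq_len(m), , drop = FALSE],
       B = fb$features[-seq_len(m), , drop = FALSE],
       expansion = fb$expansion)
}

# Independent dense grid-search oracle for the regularized objective:
# a coarse pass over the supplied grids, then a fine local pass around
# the coarse winner.
gridSearchObjective <- function(P, B, beta, grids, refineStep = 0.002) {
  beta <- rep_len(beta, ncol(P))
  empMean <- colMeans(P)
  objOf <- function(lam) {
    eta <- as.numeric(B %*% lam)
    M <- max(eta)
    -sum(lam * empMean) + M + log(sum(exp(eta - M))) +
      sum(beta * abs(lam))
  }
  searchOver <- function(grids) {
    combs <- as.matrix(do.call(expand.grid, grids))
    best <- Inf; bestLam <- NULL
    for (i in seq_len(nrow(combs))) {
      o <- objOf(combs[i, ])
      if (o < best) { best <- o; bestLam <- combs[i, ] }
    }
    list(obj = best, lam = bestLam)
  }
  coarse <- searchOver(grids)
  steps <- vapply(grids, function(g) min(diff(sort(unique(g)))), 0)
  fine <- searchOver(lapply(seq_along(grids), function(j)
    seq(coarse$lam[j] - steps[j], coarse$lam[j] + steps[j],
        by = refineStep)))
  min(coarse$obj, fine$obj)
}

# Build a constant suitability surface over a given stack's grid.
constantSurface <- function(stack, value, scale = "raw") {
  v <- matrix(NA_real_, nrow(stackMask(stack)), ncol(stackMask(stack)))
  v[stackMask(stack)] <- value
  new("SuitabilitySurface", values = v, scale = scale,
      mask = stackMask(stack), xll = stack@xll, yll = stack@yll,
      cellsize = stack@cellsize, provenance = list())
}

# Fast fit settings for permutation tests at test scale.
testFitSettings <- list(classes = "LQ", kktTol = 1e-3, tol = 1e-4,
                        maxIter = 200, nBackground = 600)
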