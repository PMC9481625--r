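#' @include AllClasses.R climate-stack.R extract.R utils.R
NULL

## 1-d Gaussian smoothing with edge reflection
conv1 <- function(x, kern, r) {
  n <- length(x)
  pad <- c(rev(x[seq_len(r)]), x, rev(x[(n - r + 1):n]))
  y <- stats::filter(pad, kern, sides = 2)
  as.numeric(y[(r + 1):(r + n)])
}

smoothField <- function(m, scale) {
  if (scale <= 0) return(m)
  r <- ceiling(3 * scale)
  kern <- stats::dnorm(seq(-r, r), sd = scale)
  kern <- kern / sum(kern)
  m <- apply(m, 2L, conv1, kern = kern, r = r)
  t(apply(m, 1L, conv1, kern = kern, r = r))
}

standardizeOverMask <- function(m, mask) {
  v <- m[mask]
  m[mask] <- (v - mean(v)) / stats::sd(v)
  m[!mask] <- NA_real_
  m
}

#' Generate a synthetic climate stack
#'
#' Each layer is an independent white-noise field, smoothed with a
#' separable Gaussian kernel of the given scale (in cells) to induce
#' spatial autocorrelation, then standardized to zero mean and unit
#' variance over the study-area mask. Consecutive disjoint layer pairs
#' (1,2), (3,4), ... are then mixed so that the second member of each pair
#' has exactly the requested sample Pearson correlation with the first
#' (the second field is first residualized against the first, so the
#' achieved correlation is exact, not approximate). Deterministic given
#' \code{seed}.
#'
#' @param nVars number of layers (>= 2)
#' @param nRows,nCols grid dimensions
#' @param smoothingScale Gaussian kernel sd in cells; 0 = no smoothing
#' @param interVarCorrelation target correlation within designated pairs,
#'   |r| < 1
#' @param seed integer RNG seed
#' @param xll,yll,cellsize grid registration (degrees); the default tile
#'   sits at British latitudes so a cell edge is a few km
#' @param mask optional logical study-area matrix (default: all cells)
#' @param varNames layer names (default ENV1..ENVn)
#' @return a \linkS4class{ClimateStack}
#' @export
generateClimateStack <- function(nVars, nRows, nCols, smoothingScale,
                                 interVarCorrelation, seed,
                                 xll = -6, yll = 49, cellsize = 0.05,
                                 mask = NULL,
                                 varNames = paste0("ENV", seq_len(nVars))) {
  if (nRows < 1 || nCols < 1) stop("grid dimensions must be positive")
  if (nVars < 2) stop("need at least 2 variables")
  if (abs(interVarCorrelation) >= 1)
    stop("|interVarCorrelation| must be < 1")
  if (smoothingScale < 0) stop("smoothingScale must be >= 0")
  if (is.null(mask)) mask <- matrix(TRUE, nRows, nCols)
  stopifnot(identical(dim(mask), as.integer(c(nRows, nCols))))
  layers <- withSeed(seed, {
    lapply(seq_len(nVars), function(k) {
      f <- matrix(stats::rnorm(nRows * nCols), nRows, nCols)
      standardizeOverMask(smoothField(f, smoothingScale), mask)
    })
  })
  rho <- interVarCorrelation
  if (rho != 0) {
    for (i in seq_len(nVars %/% 2)) {
      a <- layers[[2L * i - 1L]]; b <- layers[[2L * i]]
      av <- a[mask]; bv <- b[mask]
      resid <- bv - stats::cor(av, bv) * av
      resid <- (resid - mean(resid)) / stats::sd(resid)
      b[mask] <- rho * av + sqrt(1 - rho^2) * resid
      layers[[2L * i]] <- standardizeOverMask(b, mask)
    }
  }
  names(layers) <- varNames
  climateStack(layers, xll = xll, yll = yll, cellsize = cellsize,
               mask = mask)
}

#' Construct a NicheTruth
#'
#' @param optimum named numeric vector of per-variable optima (climate
#'   units, i.e. standardized layer units for generated stacks)
#' @param breadth named numeric vector of per-variable breadths (> 0)
#' @param allele allele label
#' @export
nicheTruth <- function(optimum, breadth, allele) {
  if (is.null(names(optimum)))
    stop("optimum must be named by climate variable")
  if (length(breadth) == 1L && length(optimum) > 1L)
    breadth <- rep(breadth, length(optimum))
  if (is.null(names(breadth))) {
    stopifnot(length(breadth) == length(optimum))
    names(breadth) <- names(optimum)
  }
  new("NicheTruth", optimum = optimum,
      breadth = breadth[names(optimum)], allele = allele)
}

#' Ground-truth suitability of a niche on a stack
#'
#' Product-Gaussian response:
#' \eqn{s(cell) = \exp(-\sum_v (z_v - \mu_v)^2 / (2\sigma_v^2))}, in
#' (0, 1], with the peak value 1 attained where every variable sits at
#' its optimum.
#'
#' @param stack a ClimateStack
#' @param niche a NicheTruth whose variables are all in the stack
#' @return a \linkS4class{SuitabilitySurface} with scale \code{"truth"}
#' @export
trueSuitability <- function(stack, niche) {
  vars <- names(niche@optimum)
  missing <- setdiff(vars, layerNames(stack))
  if (length(missing))
    stop("unknown variable(s) in niche: ", paste(missing, collapse = ", "))
  expo <- matrix(0, nrow(stack@mask), ncol(stack@mask))
  for (v in vars) {
    z <- stack@layers[, , v]
    expo <- expo + (z - niche@optimum[[v]])^2 / (2 * niche@breadth[[v]]^2)
  }
  s <- exp(-expo)
  s[!stack@mask] <- NA_real_
  newSurface(s, stack, "truth",
             provenance = list(allele = niche@allele))
}

#' Sample occurrence points from a suitability surface
#'
#' Draws cells without replacement with probability proportional to
#' suitability and places each point at its cell centre. With
#' \code{minDistanceKm > 0}, candidate draws that fall within the minimum
#' great-circle distance of an already-accepted point are rejected and
#' redrawn (the rejected cell leaves the candidate pool); sampling fails
#' with an explicit error if the retry budget is exhausted before \code{n}
#' points satisfy the constraint.
#'
#' @param surface a SuitabilitySurface (any scale; values must be
#'   non-negative)
#' @param n number of points (>= 1)
#' @param minDistanceKm minimum pairwise distance (km); 0 disables
#' @param seed integer RNG seed
#' @param allele allele label attached to the points
#' @param retryCap total draw budget when the distance filter is active
#'   (default \code{100 * n})
#' @return an \linkS4class{OccurrenceSet}
#' @export
sampleOccurrences <- function(surface, n, minDistanceKm = 0, seed,
                              allele = "A", retryCap = 100 * n) {
  stopifnot(n >= 1)
  avail <- which(surface@mask)
  if (length(avail) < n)
    stop("fewer unmasked cells than requested points")
  w <- surface@values[avail]
  if (any(w < 0)) stop("suitability must be non-negative")
  if (sum(w > 0) < n) stop("fewer positive-suitability cells than n")
  cells <- withSeed(seed, {
    if (minDistanceKm <= 0) {
      avail[sample.int(length(avail), n, prob = w)]
    } else {
      chosen <- integer(); chosenXY <- NULL
      pool <- avail; pw <- w; draws <- 0L
      while (length(chosen) < n) {
        if (draws >= retryCap || !length(pool) || sum(pw) <= 0)
          stop(sprintf(paste0("could not place %d points at pairwise ",
                              ">= %g km after %d draws"),
                       n, minDistanceKm, draws))
        draws <- draws + 1L
        i <- sample.int(length(pool), 1L, prob = pw)
        cand <- pool[i]
        xy <- cellCentres(surface, cand)
        ok <- is.null(chosenXY) ||
          all(geosphere::distHaversine(xy, chosenXY, r = 6371000) / 1000 >=
                minDistanceKm)
        if (ok) {
          chosen <- c(chosen, cand)
          chosenXY <- rbind(chosenXY, xy)
        }
        pool <- pool[-i]; pw <- pw[-i]
      }
      chosen
    }
  })
  xy <- cellCentres(surface, cells)
  occurrenceSet(xy[, 1], xy[, 2], rep(allele, n),
                provenance = sprintf("sampled from %s surface, seed %d",
                                     surface@scale, as.integer(seed)))
}

#' Build a complete synthetic world with known niche truth
#'
#' The default world emulates the study system at desk scale: a handful of
#' spatially autocorrelated, partially correlated climate layers over a
#' British-latitude tile; a cold-adapted allele (HbS-like, low optimum on
#' the temperature-like layer ENV1) and a warm-adapted allele (HbF-like,
#' high ENV1 optimum) with product-Gaussian responses; presence counts 40
#' and 57; and a "future" stack equal to the present stack plus an
#' additive warming shift on ENV1, so the warm allele's favourability must
#' expand under projection.
#'
#' @param nRows,nCols grid dimensions (default 110 x 100)
#' @param nVars number of climate layers (default 4; the first two are
#'   informative, the rest are decoys)
#' @param smoothingScale,interVarCorrelation passed to
#'   \code{\link{generateClimateStack}}
#' @param nOcc named integer vector of presence counts per allele
#' @param truths named list of \linkS4class{NicheTruth}; the default pair
#'   diverges on ENV1 and ENV2. Pass truths with identical optima to build
#'   an exchangeable (same-niche) null world.
#' @param futureShift named numeric vector of additive per-variable shifts
#'   defining the future stack; NULL for no future scenario
#' @param minDistanceKm distance filter applied when sampling occurrences
#' @param seed integer RNG seed; the whole world is reproducible from it
#' @return a \linkS4class{SyntheticWorld}
#' @export
makeSyntheticWorld <- function(nRows = 110, nCols = 100, nVars = 4,
                               smoothingScale = 4,
                               interVarCorrelation = 0.3,
                               nOcc = c(HbS = 40, HbF = 57),
                               truths = NULL,
                               futureShift = c(ENV1 = 2),
                               minDistanceKm = 0,
                               seed = 1) {
  present <- generateClimateStack(nVars, nRows, nCols, smoothingScale,
                                  interVarCorrelation, seed)
  if (is.null(truths)) {
    truths <- list(
      HbS = nicheTruth(c(ENV1 = -1, ENV2 = 0.8), 1, "HbS"),
      HbF = nicheTruth(c(ENV1 = 1, ENV2 = -0.8), 1, "HbF")
    )
    names(truths) <- names(truths)
  }
  if (is.null(names(truths)) || !identical(sort(names(truths)),
                                           sort(names(nOcc))))
    stop("truths and nOcc must be named by the same alleles")
  surfs <- lapply(truths, function(tr) trueSuitability(present, tr))
  occs <- lapply(names(truths), function(al) {
    sampleOccurrences(surfs[[al]], n = nOcc[[al]],
                      minDistanceKm = minDistanceKm,
                      seed = childSeed(seed, match(al, names(truths))),
                      allele = al)
  })
  names(occs) <- names(truths)
  if (!is.null(futureShift)) {
    fut <- present
    for (v in names(futureShift)) {
      if (!v %in% layerNames(fut))
        stop("futureShift names unknown variable: ", v)
      fut@layers[, , v] <- fut@layers[, , v] + futureShift[[v]]
    }
    hasFut <- TRUE
  } else {
    fut <- present; hasFut <- FALSE
  }
  new("SyntheticWorld", present = present, future = fut,
      hasFuture = hasFut, truths = truths, trueSurfaces = surfs,
      occurrences = occs, seed = as.integer(seed))
}

#' Write a synthetic world to disk
#'
#' Layers go out as ESRI ASCII grids, occurrences as a headered CSV, and
#' the niche truth parameters as a YAML sidecar for recovery tests.
#'
#' @param world a SyntheticWorld
#' @param dir output directory
#' @return invisible list of written paths
#' @export
writeSyntheticWorld <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- writeClimateStack(world@present, file.path(dir, "present"))
  p2 <- if (world@hasFuture)
    writeClimateStack(world@future, file.path(dir, "future")) else character()
  rec <- do.call(rbind, lapply(world@occurrences, occRecords))
  occPath <- file.path(dir, "occurrences.csv")
  utils::write.csv(rec, occPath, row.names = FALSE, quote = FALSE)
  truth <- lapply(world@truths, function(tr) list(
    allele = tr@allele,
    optimum = as.list(tr@optimum),
    breadth = as.list(tr@breadth)))
  truthPath <- file.path(dir, "niche_truth.yaml")
  yaml::write_yaml(list(seed = world@seed, truths = truth), truthPath)
  invisible(list(present = p1, future = p2, occurrences = occPath,
                 truth = truthPath))
}
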