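test_that("climate stack generation is deterministic and standardized", {
  a <- generateClimateStack(3, 20, 25, smoothingScale = 2,
                            interVarCorrelation = 0.5, seed = 9)
  b <- generateClimateStack(3, 20, 25, smoothingScale = 2,
                            interVarCorrelation = 0.5, seed = 9)
  expect_identical(a@layers, b@layers)
  for (k in 1:3) {
    v <- a@layers[, , k][a@mask]
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
})

test_that("unsmoothed uncorrelated layers are near-independent", {
  st <- generateClimateStack(3, 100, 100, smoothingScale = 0,
                             interVarCorrelation = 0, seed = 3)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    r <- cor(st@layers[, , pair[1]][st@mask],
             st@layers[, , pair[2]][st@mask])
    expect_lt(abs(r), 0.1)
  }
})

test_that("requested inter-variable correlation is achieved", {
  # designated pair = layers (1,2); residualization makes the sample r
  # exact, comfortably inside the acceptance window [0.8, 0.97]
  for (seed in 1:5) {
    st <- generateClimateStack(2, 100, 100, smoothingScale = 3,
                               interVarCorrelation = 0.9, seed = seed)
    r <- cor(st@layers[, , 1][st@mask], st@layers[, , 2][st@mask])
    expect_gt(r, 0.8); expect_lt(r, 0.97)
  }
})

test_that("generator rejects impossible arguments", {
  expect_error(generateClimateStack(2, 0, 10, 1, 0, 1), "positive")
  expect_error(generateClimateStack(2, 10, 10, 1, 1, 1), "< 1")
  expect_error(generateClimateStack(2, 10, 10, -1, 0, 1), ">= 0")
})

test_that("true suitability follows the product-Gaussian closed form", {
  z <- matrix(c(0, 1, 2, 3), 2, 2)
  st <- climateStack(list(T = z), cellsize = 1)
  # peak of the response: cell at the optimum scores exactly 1
  peak <- trueSuitability(st, nicheTruth(c(T = 2), 1, "A"))
  expect_equal(peak@values[z == 2], 1)
  # one breadth away from the optimum: exp(-1/2)
  expect_equal(peak@values[z == 3], exp(-0.5))
  expect_equal(peak@values[z == 0], exp(-2))
  # very broad niche: constant ~1 over the mask
  flat <- trueSuitability(st, nicheTruth(c(T = 0), 1e6, "A"))
  expect_true(all(abs(surfaceValues(flat, TRUE) - 1) < 1e-9))
  expect_error(trueSuitability(st, nicheTruth(c(Q = 0), 1, "A")),
               "unknown variable")
})

test_that("occurrence sampling respects suitability weights", {
  z <- matrix(0, 1, 2)
  st <- climateStack(list(T = z), cellsize = 1)
  s <- constantSurface(st, 1)
  s@values[1, 1] <- 0.8; s@values[1, 2] <- 0.2
  picks <- vapply(1:10000, function(seed) {
    occRecords(sampleOccurrences(s, 1, seed = seed))$longitude
  }, 0)
  freq1 <- mean(picks == 0.5)  # centre of cell 1
  expect_gt(freq1, 0.78); expect_lt(freq1, 0.82)
})

test_that("single-support and uniform sampling behave as expected", {
  z <- matrix(0, 2, 5)
  st <- climateStack(list(T = z), cellsize = 1)
  one <- constantSurface(st, 0)
  one@values[1, 3] <- 1
  for (seed in 1:20) {
    xy <- occRecords(sampleOccurrences(one, 1, seed = seed))
    expect_equal(cellFromXY(one, xy$longitude, xy$latitude),
                 which(one@values == 1))
  }
  # constant surface: selection frequencies uniform over the 10 cells
  unif <- constantSurface(st, 0.5)
  cells <- vapply(1:1000, function(seed) {
    xy <- occRecords(sampleOccurrences(unif, 1, seed = seed))
    cellFromXY(unif, xy$longitude, xy$latitude)
  }, 1L)
  gof <- chisq.test(tabulate(cells, 10))
  expect_gt(gof$p.value, 0.01)
})

test_that("distance-filtered sampling enforces the minimum spacing", {
  st <- generateClimateStack(2, 30, 30, 2, 0, seed = 5)
  s <- trueSuitability(st, nicheTruth(c(ENV1 = 0), 1, "A"))
  occ <- occRecords(sampleOccurrences(s, 12, minDistanceKm = 8, seed = 2))
  d <- geosphere::distHaversine(
    as.matrix(occ[c("longitude", "latitude")])[rep(1:12, each = 12), ],
    as.matrix(occ[c("longitude", "latitude")])[rep(1:12, times = 12), ],
    r = 6371000) / 1000
  d <- matrix(d, 12, 12)
  expect_true(all(d[upper.tri(d)] >= 8))
  # an impossible constraint fails loudly, naming it
  expect_error(sampleOccurrences(s, 100, minDistanceKm = 500, seed = 1),
               "km")
})

test_that("synthetic worlds are reproducible with selective sampling", {
  w1 <- divergentWorld()
  w2 <- makeSyntheticWorld(nRows = 60, nCols = 60, nVars = 4,
                           smoothingScale = 3, interVarCorrelation = 0.3,
                           nOcc = c(HbS = 40, HbF = 57),
                           futureShift = c(ENV1 = 2), seed = 42)
  expect_identical(w1@present@layers, w2@present@layers)
  expect_identical(occRecords(w1@occurrences$HbS),
                   occRecords(w2@occurrences$HbS))
  for (al in c("HbS", "HbF")) {
    occ <- w1@occurrences[[al]]
    expect_equal(nrow(occRecords(occ)), c(HbS = 40, HbF = 57)[[al]])
    cells <- cellFromXY(w1@present, occRecords(occ)$longitude,
                        occRecords(occ)$latitude)
    expect_true(all(w1@present@mask[cells]))
    # selection worked: presences sit on better-than-average habitat
    truth <- w1@trueSurfaces[[al]]
    expect_gt(mean(truth@values[cells]),
              mean(surfaceValues(truth, TRUE)))
  }
  # future stack is the present stack plus the designed ENV1 shift
  expect_equal(w1@future@layers[, , "ENV1"][w1@present@mask],
               w1@present@layers[, , "ENV1"][w1@present@mask] + 2)
})

test_that("a written world round-trips through disk", {
  w <- divergentWorld()
  dir <- withr::local_tempdir()
  paths <- writeSyntheticWorld(w, dir)
  st <- readRasterStack(paths$present, layerNames(w@present))
  expect_equal(st@layers, w@present@layers)
  occ <- readOccurrences(paths$occurrences)
  expect_equal(sum(alleleCounts(occ)), 97)
  truth <- yaml::read_yaml(paths$truth)
  expect_equal(truth$truths$HbS$optimum$ENV1, -1)
})
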