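# Shared fitted model for projection tests: cold allele on the divergent
# world, background = every cell so the training range spans the grid.
coldFit <- function() fixture("coldFit", function() {
  w <- divergentWorld()
  pv <- extractValues(w@present, w@occurrences$HbS)
  bg <- sampleBackground(w@present, sum(stackMask(w@present)), seed = 13)
  trainMaxent(pv, bg$values, classes = "LQ")
})

test_that("identity projection reproduces the training prediction", {
  w <- divergentWorld()
  fit <- coldFit()
  train <- predictSurface(fit, w@present, "cloglog")
  proj <- projectModel(fit, w@present)
  expect_identical(proj@values, train@values)
  # in-range data: nothing clamps
  expect_false(any(proj@provenance$clampingMask))
})

test_that("a warming shift degrades the cold-adapted allele", {
  w <- divergentWorld()
  fit <- coldFit()
  present <- projectModel(fit, w@present)
  future <- projectModel(fit, w@future)
  expect_lt(mean(surfaceValues(future, TRUE)),
            mean(surfaceValues(present, TRUE)))
  # the future ENV1 values exceed the training range, so clamping bites
  expect_true(any(future@provenance$clampingMask))
})

test_that("surface averaging is exact and envelope-bounded", {
  w <- divergentWorld()
  one <- constantSurface(w@present, 0.2, scale = "cloglog")
  two <- constantSurface(w@present, 0.6, scale = "cloglog")
  avg <- averageSurfaces(list(one, two))
  expect_equal(unique(surfaceValues(avg, TRUE)), 0.4)
  expect_equal(averageSurfaces(list(one))@values, one@values)
  # perturbed ensemble members: the mean sits inside the min/max envelope
  fit <- coldFit()
  members <- lapply(c(0.5, 1, 1.5, 2), function(shift) {
    fut <- w@present
    fut@layers[, , "ENV1"] <- fut@layers[, , "ENV1"] + shift
    projectModel(fit, fut)
  })
  ens <- averageSurfaces(members)
  lo <- Reduce(pmin, lapply(members, function(s) surfaceValues(s, TRUE)))
  hi <- Reduce(pmax, lapply(members, function(s) surfaceValues(s, TRUE)))
  v <- surfaceValues(ens, TRUE)
  expect_true(all(v >= lo - 1e-12 & v <= hi + 1e-12))
  bad <- constantSurface(w@present, 0.5, scale = "raw")
  expect_error(averageSurfaces(list(one, bad)), "scales")
})

test_that("training thresholds use nearest-rank percentiles", {
  z <- matrix(0, 1, 10)
  st <- climateStack(list(T = z), cellsize = 1)
  s <- constantSurface(st, 0, scale = "cloglog")
  s@values[1, ] <- seq(0.1, 1, by = 0.1)
  occ <- occurrenceSet(seq(0.5, 9.5), rep(0.5, 10), rep("A", 10))
  th <- trainingThresholds(s, occ)
  # n = 10: ceil(0.05*10) = 1 and ceil(0.10*10) = 1 -> all = v[1]
  expect_equal(th@mtp, 0.1)
  expect_equal(th@p5, 0.1)
  expect_equal(th@p10, 0.1)
  # n = 100 distinct ascending values: p5 = v[5], p10 = v[10]
  z100 <- matrix(0, 1, 100)
  st100 <- climateStack(list(T = z100), cellsize = 1)
  s100 <- constantSurface(st100, 0, scale = "cloglog")
  v <- sort(runif(100)); s100@values[1, ] <- v
  occ100 <- occurrenceSet(seq(0.5, 99.5), rep(0.5, 100), rep("A", 100))
  th100 <- trainingThresholds(s100, occ100)
  expect_equal(th100@mtp, v[1])
  expect_equal(th100@p5, v[5])
  expect_equal(th100@p10, v[10])
  # constant presences collapse all three thresholds
  sC <- constantSurface(st, 0.42, scale = "cloglog")
  thC <- trainingThresholds(sC, occ)
  expect_equal(c(thC@mtp, thC@p5, thC@p10), rep(0.42, 3))
  expect_error(trainingThresholds(s, occurrenceSet(50, 50, "A")),
               "outside")
})

test_that("suitability classes are inclusive and nested", {
  z <- matrix(0, 1, 4)
  st <- climateStack(list(T = z), cellsize = 1)
  s <- constantSurface(st, 0, scale = "cloglog")
  s@values[1, ] <- c(0.1, 0.3, 0.5, 0.9)
  th <- new("ThresholdSet", mtp = 0.2, p5 = 0.4, p10 = 0.6,
            scale = "cloglog")
  cls <- classifySuitability(s, th)
  expect_equal(as.integer(cls[1, ]), c(0L, 1L, 2L, 3L))
  # a cell exactly at p10 is high (inclusive lower bound)
  s@values[1, 1] <- 0.6
  expect_equal(classifySuitability(s, th)[1, 1], 3L)
  areas <- classAreas(classifySuitability(s, th))
  expect_gte(sum(areas[c("marginal", "moderate", "high")]),
             sum(areas[c("moderate", "high")]))
  expect_gte(sum(areas[c("moderate", "high")]), areas[["high"]])
})

test_that("favourability percents behave under swaps and transforms", {
  w <- divergentWorld()
  fit <- coldFit()
  base <- projectModel(fit, w@present)
  shifted <- base
  shifted@values <- pmin(base@values + 0.1, 1)
  fav <- relativeFavourability(shifted, base, alleles = c("up", "base"))
  expect_equal(unname(fav@percents["up"]), 100)
  # antisymmetry up to ties
  f1 <- relativeFavourability(base, shifted, alleles = c("a", "b"))
  expect_equal(unname(f1@percents["b"]), 100)
  expect_equal(sum(fav@percents), 100)
  # invariance under a common strictly increasing transform
  wWarm <- divergentWorld()
  pvF <- extractValues(wWarm@present, wWarm@occurrences$HbF)
  bgAll <- sampleBackground(wWarm@present,
                            sum(stackMask(wWarm@present)), seed = 14)
  fitF <- trainMaxent(pvF, bgAll$values, classes = "LQ")
  sS <- projectModel(fit, wWarm@present)
  sF <- projectModel(fitF, wWarm@present)
  f0 <- relativeFavourability(sS, sF, alleles = c("HbS", "HbF"))
  tS <- sS; tS@values <- sqrt(sS@values)
  tF <- sF; tF@values <- sqrt(sF@values)
  fT <- relativeFavourability(tS, tF, alleles = c("HbS", "HbF"))
  expect_equal(f0@percents, fT@percents)
  expect_false(isTRUE(all.equal(unname(f0@percents[["HbF"]]), 0)))
})

test_that("warming expands the warm allele's favoured area", {
  w <- divergentWorld()
  fitS <- coldFit()
  pvF <- extractValues(w@present, w@occurrences$HbF)
  bgAll <- sampleBackground(w@present, sum(stackMask(w@present)),
                            seed = 14)
  fitF <- trainMaxent(pvF, bgAll$values, classes = "LQ")
  favNow <- relativeFavourability(projectModel(fitS, w@present),
                                  projectModel(fitF, w@present),
                                  alleles = c("HbS", "HbF"))
  favFut <- relativeFavourability(projectModel(fitS, w@future),
                                  projectModel(fitF, w@future),
                                  alleles = c("HbS", "HbF"))
  expect_gt(unname(favFut@percents["HbF"]),
            unname(favNow@percents["HbF"]))
})
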