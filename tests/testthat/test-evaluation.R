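test_that("AUC follows the Mann-Whitney definition", {
  expect_equal(aucScore(c(0.9, 0.8), c(0.1, 0.2)), 1)
  expect_equal(aucScore(rep(0.5, 4), rep(0.5, 6)), 0.5)
  # two pairs: (0.7 > 0.5) wins, (0.3 < 0.5) loses -> (1 + 0) / 2
  expect_equal(aucScore(c(0.7, 0.3), 0.5), 0.5)
  expect_error(aucScore(numeric(), 1), "non-empty")
  # invariance under a strictly increasing transform
  set.seed(1)
  p <- runif(30); b <- runif(50)
  expect_equal(aucScore(exp(3 * p), exp(3 * b)), aucScore(p, b))
})

test_that("partial-AUC ratio separates signal from chance", {
  # perfect separation: ratio at its E-dependent maximum (about 2), p = 0
  perfect <- partialAucRatio(runif(50, 0.8, 1), runif(200, 0, 0.5),
                             seed = 1)
  expect_gt(perfect$meanRatio, 1.8)
  expect_lte(perfect$meanRatio, 2.06)
  expect_equal(perfect$pValue, 0)
  # null calibration: presence scores drawn from the background law
  set.seed(42)
  nullRes <- partialAucRatio(rnorm(200), rnorm(200), nBoot = 100,
                             seed = 7)
  expect_gt(nullRes$meanRatio, 0.9)
  expect_lt(nullRes$meanRatio, 1.1)
  # deterministic given the seed
  again <- partialAucRatio(rnorm(200), rnorm(200), nBoot = 100, seed = 7)
  expect_error(partialAucRatio(0.5, runif(10), seed = 1), "too few")
  expect_error(partialAucRatio(runif(10), runif(10), omissionE = 0.7),
               "omissionE")
})

test_that("partial-AUC ratio is reproducible from its seed", {
  set.seed(99)
  p <- rnorm(80, 0.5); b <- rnorm(150)
  r1 <- partialAucRatio(p, b, seed = 11)
  r2 <- partialAucRatio(p, b, seed = 11)
  expect_identical(r1$ratios, r2$ratios)
})

test_that("subsampling replicates partition the indices correctly", {
  rs <- subsampleReplicates(10, 50, testFraction = 0.3, seed = 2)
  expect_length(rs$splits, 50)
  for (sp in rs$splits) {
    expect_length(sp$test, 3)
    expect_length(sp$train, 7)
    expect_setequal(c(sp$train, sp$test), 1:10)
    expect_length(intersect(sp$train, sp$test), 0)
  }
  expect_identical(subsampleReplicates(10, 50, 0.3, seed = 2)$splits,
                   rs$splits)
  expect_error(subsampleReplicates(3, 5, 0.01), "impossible")
  expect_error(subsampleReplicates(10, 5, 1.2), "testFraction")
})

test_that("jackknife gain identifies informative vs decoy variables", {
  w <- fixture("jackknifeWorld", function() {
    makeSyntheticWorld(nRows = 80, nCols = 80, nVars = 4,
                       smoothingScale = 2, interVarCorrelation = 0,
                       nOcc = c(HbS = 57, HbF = 57),
                       futureShift = NULL, seed = 21)
  })
  pv <- extractValues(w@present, w@occurrences$HbS)
  bg <- sampleBackground(w@present, 1000, seed = 5)
  jk <- jackknifeImportance(pv, bg$values,
                            settings = list(classes = "LQ"))
  expect_setequal(jk$variable, paste0("ENV", 1:4))
  # decoy variables (ENV3, ENV4 play no role in the niche truth)
  expect_lte(jk$gainAlone[jk$variable == "ENV3"], 0.05)
  expect_lte(jk$gainAlone[jk$variable == "ENV4"], 0.05)
  # the informative axes dominate every decoy
  expect_gt(jk$gainAlone[jk$variable == "ENV1"], 0.1)
  expect_gt(jk$gainAlone[jk$variable == "ENV2"], 0.1)
  # nesting: the full model cannot lose to any leave-one-out model
  expect_true(all(attr(jk, "fullGain") >= jk$gainWithout - 1e-6))
})

test_that("a duplicated informative variable is redundant", {
  w <- divergentWorld()
  pv <- extractValues(w@present, w@occurrences$HbS)[, c("ENV1", "ENV2")]
  bg <- sampleBackground(w@present, 800, seed = 6)$values[, c("ENV1",
                                                              "ENV2")]
  pv2 <- cbind(pv, ENV1copy = pv[, "ENV1"])
  bg2 <- cbind(bg, ENV1copy = bg[, "ENV1"])
  jk <- jackknifeImportance(pv2, bg2, settings = list(classes = "LQ"))
  full <- attr(jk, "fullGain")
  dropCopy <- jk$gainWithout[jk$variable == "ENV1copy"]
  expect_lt(abs(full - dropCopy), 1e-3)
})

test_that("variable selection keeps informative, decorrelated variables", {
  w <- fixture("selectWorld", function() {
    makeSyntheticWorld(nRows = 50, nCols = 50, nVars = 6,
                       smoothingScale = 3, interVarCorrelation = 0,
                       nOcc = c(HbS = 40, HbF = 57),
                       futureShift = NULL, seed = 7)
  })
  vs <- selectVariables(w@present, w@occurrences$HbS, rThreshold = 0.8,
                        targetK = 4,
                        settings = list(classes = "LQ",
                                        nBackground = 600), seed = 3)
  # 2 informative + 4 noise variables: the informative pair survives
  expect_true(all(c("ENV1", "ENV2") %in% vs$finalVariables))
  expect_length(vs$finalVariables, 4)
  expect_length(vs$steps, 2)
  cm <- vs$correlation; diag(cm) <- 0
  expect_true(all(abs(cm) <= 0.8))
  expect_error(selectVariables(w@present, w@occurrences$HbS,
                               targetK = 10), "fewer variables")
})

test_that("the correlation filter removes exactly one of a perfect pair", {
  w <- divergentWorld()
  # build a stack where ENV2 is a perfect copy of ENV1
  layers <- list(ENV1 = w@present@layers[, , "ENV1"],
                 ENV2 = w@present@layers[, , "ENV1"],
                 ENV3 = w@present@layers[, , "ENV3"])
  st <- climateStack(layers, xll = w@present@xll, yll = w@present@yll,
                     cellsize = w@present@cellsize)
  vs <- selectVariables(st, w@occurrences$HbS, rThreshold = 0.8,
                        targetK = 3,
                        settings = list(classes = "LQ",
                                        nBackground = 400), seed = 1)
  expect_equal(sum(c("ENV1", "ENV2") %in% vs$finalVariables), 1)
  # threshold 1.0 disables the filter entirely
  vs2 <- selectVariables(st, w@occurrences$HbS, rThreshold = 1,
                         targetK = 3,
                         settings = list(classes = "LQ",
                                         nBackground = 400), seed = 1)
  expect_length(vs2$finalVariables, 3)
})

test_that("noise-only models hover at chance AUC", {
  w <- fixture("noiseWorld", function() {
    makeSyntheticWorld(nRows = 50, nCols = 50, nVars = 2,
                       smoothingScale = 2, interVarCorrelation = 0,
                       nOcc = c(HbS = 40, HbF = 40),
                       truths = list(
                         HbS = nicheTruth(c(ENV1 = 0), 1e6, "HbS"),
                         HbF = nicheTruth(c(ENV1 = 0), 1e6, "HbF")),
                       futureShift = NULL, seed = 12)
  })
  # flat truth: presences carry no climate signal
  pv <- extractValues(w@present, w@occurrences$HbS)
  bg <- sampleBackground(w@present, 600, seed = 2)
  rs <- subsampleReplicates(nrow(pv), 20, 0.25, seed = 3)
  aucs <- vapply(rs$splits, function(sp) {
    fit <- trainMaxent(pv[sp$train, ], bg$values, classes = "LQ",
                       kktTol = 1e-3)
    aucScore(
      as.numeric(predict(fit, pv[sp$test, , drop = FALSE],
                         outputScale = "cloglog")),
      as.numeric(predict(fit, bg$values, outputScale = "cloglog")))
  }, 0)
  expect_gt(mean(aucs), 0.4); expect_lt(mean(aucs), 0.6)
})
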