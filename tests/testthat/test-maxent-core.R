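test_that("feature expansion matches its closed forms", {
  v <- cbind(a = c(0, 5, 10), b = c(-2, 0, 2))
  fb <- buildFeatures(v, "LQP")
  # min-max scaling: a = 5 on [0, 10] -> 0.5
  expect_equal(unname(fb$features[2, "a"]), 0.5)
  expect_equal(unname(fb$features[2, "a^2"]), 0.25)
  expect_equal(unname(fb$features[2, "a*b"]), 0.25)
  # 2 variables, {linear, quadratic, product}: 2 + 2 + 1 = 5 columns
  expect_equal(ncol(fb$features), 5)
  expect_true(all(fb$features >= 0 & fb$features <= 1))
})

test_that("hinge features follow the knot formulas", {
  v <- cbind(x = seq(0, 1, by = 0.25))
  fb <- buildFeatures(v, "H", nHingeKnots = 3)
  # interior evenly spaced knots on the scaled range: 0.25, 0.5, 0.75
  expect_equal(fb$expansion$hingeKnots, c(0.25, 0.5, 0.75))
  # forward hinge, knot 0.5, value 0.75: (0.75-0.5)/(1-0.5) = 0.5
  expect_equal(unname(fb$features[4, "hf(x,0.5000)"]), 0.5)
  # reverse hinge, knot 0.5, value 0.25: (0.5-0.25)/0.5 = 0.5
  expect_equal(unname(fb$features[2, "hr(x,0.5000)"]), 0.5)
  expect_equal(ncol(fb$features), 6)  # 3 forward + 3 reverse
  expect_error(buildFeatures(v, "H", nHingeKnots = 1), "nHingeKnots")
  expect_error(buildFeatures(cbind(x = rep(2, 5)), "L"), "zero-variance")
})

test_that("auto feature classes follow the presence-count rule", {
  expect_equal(autoFeatureClasses(9), "linear")
  expect_equal(autoFeatureClasses(12), c("linear", "quadratic"))
  expect_equal(autoFeatureClasses(40), c("linear", "quadratic", "hinge"))
  expect_equal(autoFeatureClasses(80),
               c("linear", "quadratic", "product", "hinge"))
})

test_that("a fully penalized fit collapses to the uniform model", {
  pr <- smallFitProblem()
  fit <- fitMaxent(pr$P, pr$B, beta = rep(1e6, ncol(pr$P)))
  expect_true(all(fit@lambda == 0))
  expect_equal(fit@H, log(nrow(pr$B)))
  raw <- predictScores(fit, pr$B, outputScale = "raw", isFeatures = TRUE)
  expect_equal(as.numeric(raw), rep(1 / nrow(pr$B), nrow(pr$B)))
  # uniform model: cloglog = 1 - exp(-1) everywhere
  cll <- predictScores(fit, pr$B, outputScale = "cloglog",
                       isFeatures = TRUE)
  expect_equal(as.numeric(cll), rep(1 - exp(-1), nrow(pr$B)),
               tolerance = 1e-12)
})

test_that("an unpenalized binary feature matches its empirical mean", {
  # presences all carry the feature; half the background does
  P <- matrix(1, 20, 1, dimnames = list(NULL, "f"))
  B <- matrix(rep(c(0, 1), 100), ncol = 1, dimnames = list(NULL, "f"))
  fit <- fitMaxent(P, B, beta = 1e-9, maxIter = 5000, kktTol = 1e-4,
                   tol = 1e-9)
  w <- exp(as.numeric(B %*% fit@lambda))
  modelMean <- sum(w * B[, 1]) / sum(w)
  expect_gt(modelMean, 0.99)
  # independent 1-d grid-search oracle on the same convex problem
  oracle <- gridSearchObjective(P, B, 1e-9,
                                list(seq(0, 20, by = 0.01)))
  expect_lt(abs(fit@meta$objective - oracle), 1e-3)
})

test_that("the objective sequence is non-increasing", {
  pr <- smallFitProblem()
  fit <- fitMaxent(pr$P, pr$B)
  expect_true(all(diff(fit@meta$objTrace) <= 1e-12))
  expect_equal(fit@meta$objTrace[1], log(nrow(pr$B)))
})

test_that("coordinate descent matches a dense grid search", {
  pr <- smallFitProblem()      # LQ on one variable: 2 features
  beta <- regularizationWeights(pr$P, c("linear", "quadratic"), 1)
  fit <- fitMaxent(pr$P, pr$B, beta = beta, kktTol = 1e-8, tol = 1e-12,
                   maxIter = 5000)
  oracle <- gridSearchObjective(pr$P, pr$B, beta,
                                list(seq(-30, 30, 0.25),
                                     seq(-30, 30, 0.25)))
  expect_lt(abs(fit@meta$objective - oracle), 1e-3)
})

test_that("fits satisfy the KKT stationarity conditions", {
  for (seed in c(2, 11, 23)) {
    set.seed(seed)
    m <- 25; n <- 400
    vals <- rbind(cbind(x = rnorm(m, 1), y = rnorm(m, -0.5)),
                  cbind(x = rnorm(n), y = rnorm(n)))
    fb <- buildFeatures(vals, "LQ")
    P <- fb$features[1:m, ]; B <- fb$features[-(1:m), ]
    beta <- regularizationWeights(P, featureColumnClasses(fb$expansion))
    fit <- fitMaxent(P, B, beta = beta, kktTol = 1e-8, tol = 1e-12,
                     maxIter = 5000)
    w <- exp(as.numeric(B %*% fit@lambda)); w <- w / sum(w)
    gap <- abs(colMeans(P) - as.numeric(crossprod(B, w)))
    expect_true(all(gap <= beta + 1e-6))
  }
})

test_that("fit preconditions are enforced", {
  pr <- smallFitProblem()
  expect_error(fitMaxent(pr$P[1, , drop = FALSE], pr$B), "at least 2")
  expect_error(fitMaxent(pr$B, pr$P), "strictly larger")
  vdeg <- matrix(c(rep(1, 5), runif(50)), ncol = 1,
                 dimnames = list(NULL, "x"))
  expect_error(trainMaxent(vdeg[1:5, , drop = FALSE],
                           vdeg[-(1:5), , drop = FALSE]),
               "degenerate")
})

test_that("raw predictions normalize and cumulative follows its definition", {
  pr <- smallFitProblem()
  fit <- fitMaxent(pr$P, pr$B)
  raw <- as.numeric(predictScores(fit, pr$B, outputScale = "raw",
                                  isFeatures = TRUE))
  expect_equal(sum(raw), 1, tolerance = 1e-9)
  cum <- as.numeric(predictScores(fit, pr$B, outputScale = "cumulative",
                                  isFeatures = TRUE))
  expect_equal(cum[which.max(raw)], 1)
  expect_equal(cum[which.min(raw)],
               sum(raw[raw <= min(raw)]))
  expect_true(all(cum >= 0 & cum <= 1))
})

test_that("clamping is a no-op on in-range training data", {
  w <- divergentWorld()
  pv <- extractValues(w@present, w@occurrences$HbS)
  # background = every unmasked cell, so the training range spans the
  # whole prediction domain by construction
  bg <- sampleBackground(w@present, sum(stackMask(w@present)), seed = 3)
  fit <- trainMaxent(pv, bg$values, classes = "LQ")
  on <- predictSurface(fit, w@present, "cloglog", clamp = TRUE)
  off <- predictSurface(fit, w@present, "cloglog", clamp = FALSE)
  expect_identical(on@values, off@values)
  expect_length(on@provenance$clampedCells, 0)
})

test_that("AICc matches its closed form and invalidity rule", {
  # uniform model over a 100-cell landscape with 10 presences: K = 0,
  # lnL = 10 ln(1/100), AICc = -2 lnL = 92.103
  L <- matrix(runif(100), ncol = 1, dimnames = list(NULL, "x"))
  P <- L[1:10, , drop = FALSE]
  unif <- fitMaxent(P, L[11:100, , drop = FALSE], beta = 1e9)
  sc <- aicc(unif, P, L)
  expect_equal(sc$K, 0)
  expect_equal(sc$lnL, 10 * log(0.01))
  expect_equal(sc$aicc, 92.103, tolerance = 1e-3)
  expect_true(sc$valid)
  # a zero-coefficient feature cannot change AICc
  P2 <- cbind(P, y = 0.5 * P[, 1])
  L2 <- cbind(L, y = 0.5 * L[, 1])
  unif2 <- fitMaxent(P2, L2[11:100, ], beta = 1e9)
  expect_equal(aicc(unif2, P2, L2)$aicc, sc$aicc)
  # n <= K + 1 marks the candidate invalid
  fit <- fitMaxent(matrix(c(1, 0.9), 2, 1,
                          dimnames = list(NULL, "x")),
                   L[1:50, , drop = FALSE], beta = 1e-6)
  expect_gte(sum(fit@lambda != 0), 1)
  expect_false(aicc(fit, matrix(c(1, 0.9), 2, 1), L)$valid)
  expect_error(aicc(unif, P[0, , drop = FALSE], L), "zero presences")
})

test_that("AICc tuning picks quadratic features for a Gaussian niche", {
  w <- divergentWorld()
  pv <- extractValues(w@present, w@occurrences$HbF)
  bg <- sampleBackground(w@present, 1000, seed = 4)
  tuned <- tuneMaxent(pv, bg$values, featureSets = list("L", "LQ"),
                      multipliers = c(1, 2))
  expect_true(grepl("Q", tuned$classes))
  expect_equal(nrow(tuned$table), 4)
  # single candidate wins trivially
  solo <- tuneMaxent(pv, bg$values, featureSets = list("LQ"),
                     multipliers = 1)
  expect_equal(solo$classes, "LQ")
  expect_equal(solo$multiplier, 1)
})

test_that("models serialize and restore losslessly", {
  w <- divergentWorld()
  pv <- extractValues(w@present, w@occurrences$HbS)
  bg <- sampleBackground(w@present, 500, seed = 9)
  fit <- trainMaxent(pv, bg$values, classes = "LQH")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeMaxentModel(fit, path)
  back <- readMaxentModel(path)
  expect_equal(back@lambda, fit@lambda)
  expect_equal(back@Z, fit@Z)
  s1 <- predictSurface(fit, w@present)
  s2 <- predictSurface(back, w@present)
  expect_equal(s1@values, s2@values)
})
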