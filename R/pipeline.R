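#' @include AllClasses.R evaluation.R overlap.R projection.R serialize.R
NULL

#' Default pipeline configuration
#'
#' Defaults mirror the study protocol: 10-km thinning, reiterative
#' jackknife to 4 variables with an |r| > 0.8 collinearity filter, AICc
#' tuning over feature classes and multipliers {0.5, 1, 2, 4}, 50
#' subsampling replicates at 25\% test fraction, 100 randomizations for
#' the overlap tests, and 10,000 background points.
#'
#' @return nested list of settings; override any entry via
#'   \code{\link{readRunConfig}} or by editing the list
#' @export
defaultRunConfig <- function() {
  list(
    alleles = c("HbS", "HbF"),
    thinKm = 10,
    variableSelection = list(rThreshold = 0.8, targetK = 4,
                             nBackground = 1000),
    tuning = list(featureSets = list("L", "LQ", "LQH"),
                  multipliers = c(0.5, 1, 2, 4)),
    replicates = list(n = 50, testFraction = 0.25),
    randomizations = 100,
    nBackground = 10000,
    nHingeKnots = 8,
    fit = list(tol = 1e-5, maxIter = 500, kktTol = 1e-4),
    pauc = list(omissionE = 0.05, nBoot = 100, resampleFraction = 0.5),
    runOverlapTests = TRUE,
    seed = 1
  )
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Entries missing from the file take the values of
#' \code{\link{defaultRunConfig}}. Input paths (\code{occurrences},
#' \code{stacks$present$paths} + \code{variables},
#' \code{stacks$scenarios}) are resolved by \code{\link{runPipeline}}.
#'
#' @param path YAML file
#' @return config list
#' @export
readRunConfig <- function(path) {
  mergeConfig(defaultRunConfig(), yaml::read_yaml(path))
}

resolveStack <- function(x) {
  if (is(x, "ClimateStack")) return(x)
  if (is.list(x) && !is.null(x$paths))
    return(readRasterStack(unlist(x$paths), unlist(x$variables)))
  stop("cannot resolve a climate stack from config entry")
}

subsetOcc <- function(occ, idx) {
  out <- occRecords(occ)[idx, , drop = FALSE]
  rownames(out) <- NULL
  new("OccurrenceSet", records = out, provenance = occ@provenance)
}

## replicate-mean cloglog surface + per-replicate test AUC/pAUC
replicateModels <- function(pres, bgValues, stack, settings, nRep,
                            testFraction, pauc, seed) {
  presVals <- extractValues(stack, pres)
  n <- nrow(presVals)
  reps <- subsampleReplicates(n, nRep, testFraction, seed = seed)
  maskCells <- which(stack@mask)
  maskValues <- valuesAtCells(stack, maskCells)
  acc <- 0; aucs <- numeric(nRep); paucs <- numeric(nRep)
  for (r in seq_len(nRep)) {
    sp <- reps$splits[[r]]
    fit <- fitFromValues(presVals[sp$train, , drop = FALSE], bgValues,
                         settings)
    sc <- predictScores(fit, maskValues, outputScale = "cloglog")
    acc <- acc + as.numeric(sc)
    bgScores <- as.numeric(predictScores(fit, bgValues,
                                         outputScale = "cloglog"))
    testScores <- as.numeric(predictScores(
      fit, presVals[sp$test, , drop = FALSE], outputScale = "cloglog"))
    aucs[r] <- aucScore(testScores, bgScores)
    paucs[r] <- partialAucRatio(testScores, bgScores,
                                omissionE = pauc$omissionE,
                                nBoot = pauc$nBoot,
                                resampleFraction = pauc$resampleFraction,
                                seed = childSeed(seed, 5000L + r)
                                )$meanRatio
  }
  v <- matrix(NA_real_, nrow(stack@mask), ncol(stack@mask))
  v[maskCells] <- acc / nRep
  meanSurf <- newSurface(v, stack, "cloglog",
                         provenance = list(replicates = nRep))
  ## full-data fit for projection and environmental-space overlap
  fullFit <- fitFromValues(presVals, bgValues, settings)
  list(meanSurface = meanSurf, auc = aucs, pauc = paucs,
       replicates = reps, fullFit = fullFit)
}

projectScenario <- function(fullFit, members, outputScale = "cloglog") {
  surfs <- lapply(members, function(st)
    projectModel(fullFit, st, clamp = TRUE, outputScale = outputScale))
  averageSurfaces(surfs)
}

#' Run the full genic-distribution-modelling pipeline
#'
#' Thins the occurrences, selects two climate-variable sets by
#' reiterative jackknife (Set 1 trained on the first allele, Set 2 on
#' the second), tunes feature classes and regularization by AICc,
#' fits subsampling-replicate models per allele and set, evaluates them
#' (AUC, partial-AUC ratio), projects to each future scenario member and
#' averages per scenario, derives training-presence thresholds and
#' classified maps, computes relative favourability between the alleles,
#' and runs Schoener's D overlap with identity and background tests.
#' Reruns with the same config and seed are identical.
#'
#' @param config a config list (see \code{\link{defaultRunConfig}});
#'   \code{config$stacks$present} must resolve to a ClimateStack, and
#'   \code{config$occurrences} to an OccurrenceSet or a file path.
#'   \code{config$stacks$scenarios} is a named list; each entry is a
#'   list of member ClimateStacks (or path lists). Omit it to skip the
#'   projection and future-favourability stages.
#' @param outdir output directory; tables, grids and YAML results are
#'   written beneath it alongside a run log with the config hash
#' @return invisible list of results (surfaces, models, evaluation
#'   tables, favourability maps, overlap results)
#' @export
runPipeline <- function(config, outdir = tempfile("alleleNiche_run_")) {
  cfg <- mergeConfig(defaultRunConfig(), config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outdir, "run.log")
  logLine <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = logPath, append = TRUE)
  cfgHash <- sum(utf8ToInt(paste(utils::capture.output(
    utils::str(cfg[setdiff(names(cfg), c("stacks", "occurrences"))])),
    collapse = "")))
  logLine("alleleNiche pipeline; seed %d; config hash %d",
          cfg$seed, cfgHash)

  stage <- "inputs"
  res <- try({
    present <- resolveStack(cfg$stacks$present)
    occ <- cfg$occurrences
    if (is.character(occ)) occ <- readOccurrences(occ)
    alleles <- cfg$alleles

    stage <- "thinning"
    thinned <- thinOccurrences(occ, cfg$thinKm)
    counts <- alleleCounts(thinned)
    logLine("thinned to %d records (%s)", nrow(occRecords(thinned)),
            paste(sprintf("%s=%d", names(counts), counts),
                  collapse = ", "))
    byAllele <- lapply(alleles, function(al)
      subsetOcc(thinned, which(occRecords(thinned)$allele == al)))
    names(byAllele) <- alleles

    stage <- "variable selection"
    fitSettings <- c(list(nHingeKnots = cfg$nHingeKnots), cfg$fit)
    varSets <- lapply(seq_along(alleles), function(i) {
      vs <- selectVariables(
        present, byAllele[[i]],
        rThreshold = cfg$variableSelection$rThreshold,
        targetK = cfg$variableSelection$targetK,
        settings = c(fitSettings,
                     list(nBackground = cfg$variableSelection$nBackground)),
        seed = childSeed(cfg$seed, 100L + i))
      logLine("Set %d (trained on %s): %s", i, alleles[i],
              paste(vs$finalVariables, collapse = ", "))
      vs
    })
    names(varSets) <- paste0("set", seq_along(alleles))

    stage <- "background"
    bg <- sampleBackground(present, min(cfg$nBackground,
                                        sum(present@mask)),
                           seed = childSeed(cfg$seed, 200L))

    stage <- "tuning and replicate fits"
    perSet <- lapply(names(varSets), function(sn) {
      vars <- varSets[[sn]]$finalVariables
      bgV <- bg$values[, vars, drop = FALSE]
      out <- lapply(alleles, function(al) {
        presV <- extractValues(present, byAllele[[al]])[, vars,
                                                        drop = FALSE]
        tuned <- tuneMaxent(presV, bgV,
                            featureSets = cfg$tuning$featureSets,
                            multipliers = cfg$tuning$multipliers,
                            nHingeKnots = cfg$nHingeKnots,
                            tol = cfg$fit$tol, maxIter = cfg$fit$maxIter,
                            kktTol = cfg$fit$kktTol)
        settings <- c(fitSettings,
                      list(classes = tuned$classes,
                           regMultiplier = tuned$multiplier))
        sub <- presentSubStack(present, vars)
        rep <- replicateModels(byAllele[[al]], bgV, sub, settings,
                               nRep = cfg$replicates$n,
                               testFraction = cfg$replicates$testFraction,
                               pauc = cfg$pauc,
                               seed = childSeed(cfg$seed, 300L +
                                                  match(al, alleles)))
        logLine("%s %s: classes %s mult %g; mean AUC %.3f, mean pAUC %.3f",
                sn, al, tuned$classes, tuned$multiplier,
                mean(rep$auc), mean(rep$pauc))
        c(rep, list(tuned = tuned, settings = settings, vars = vars))
      })
      names(out) <- alleles
      out
    })
    names(perSet) <- names(varSets)

    stage <- "thresholds and present favourability"
    set1 <- perSet$set1
    thresholds <- lapply(alleles, function(al)
      trainingThresholds(set1[[al]]$meanSurface, byAllele[[al]]))
    names(thresholds) <- alleles
    classified <- lapply(alleles, function(al)
      classifySuitability(set1[[al]]$meanSurface, thresholds[[al]]))
    names(classified) <- alleles
    favPresent <- relativeFavourability(set1[[alleles[1]]]$meanSurface,
                                        set1[[alleles[2]]]$meanSurface,
                                        alleles = alleles)
    logLine("present favourability: %s %.1f%%, %s %.1f%%",
            alleles[1], favPresent@percents[1],
            alleles[2], favPresent@percents[2])

    stage <- "scenario projection"
    scenarios <- cfg$stacks$scenarios
    favFuture <- list(); scenarioSurfaces <- list()
    if (!is.null(scenarios)) {
      for (scn in names(scenarios)) {
        members <- lapply(scenarios[[scn]], resolveStack)
        surfs <- lapply(alleles, function(al)
          projectScenario(set1[[al]]$fullFit,
                          lapply(members, presentSubStack,
                                 vars = set1[[al]]$vars)))
        names(surfs) <- alleles
        scenarioSurfaces[[scn]] <- surfs
        favFuture[[scn]] <- relativeFavourability(
          surfs[[alleles[1]]], surfs[[alleles[2]]], alleles = alleles)
        logLine("%s favourability: %s %.1f%%, %s %.1f%%", scn,
                alleles[1], favFuture[[scn]]@percents[1],
                alleles[2], favFuture[[scn]]@percents[2])
      }
    } else logLine("no scenarios configured; projection stage skipped")

    stage <- "niche overlap"
    dGeo <- schoenerD(set1[[alleles[1]]]$meanSurface,
                      set1[[alleles[2]]]$meanSurface)
    dEnv <- vapply(names(perSet), function(sn)
      schoenerDEnvironment(perSet[[sn]][[alleles[1]]]$fullFit,
                           perSet[[sn]][[alleles[2]]]$fullFit,
                           nPoints = max(100, cfg$nBackground),
                           seed = childSeed(cfg$seed, 400L)), 0)
    logLine("Schoener's D: geographic %.3f; environmental %s", dGeo,
            paste(sprintf("%s=%.3f", names(dEnv), dEnv), collapse = ", "))
    idTest <- bgTests <- NULL
    if (isTRUE(cfg$runOverlapTests)) {
      testSettings <- c(fitSettings,
                        list(classes = set1[[alleles[1]]]$settings$classes,
                             regMultiplier =
                               set1[[alleles[1]]]$settings$regMultiplier,
                             nBackground =
                               cfg$variableSelection$nBackground))
      sub1 <- presentSubStack(present, set1[[alleles[1]]]$vars)
      idTest <- identityTest(byAllele[[alleles[1]]],
                             byAllele[[alleles[2]]], sub1,
                             modelSettings = testSettings,
                             nReps = cfg$randomizations,
                             seed = childSeed(cfg$seed, 500L))
      logLine("identity test: D = %.3f, p = %.4f",
              idTest@observedD, idTest@pValue)
      bgTests <- list(
        AvsB = backgroundTest(byAllele[[alleles[1]]],
                              byAllele[[alleles[2]]], sub1,
                              modelSettings = testSettings,
                              nReps = cfg$randomizations,
                              seed = childSeed(cfg$seed, 600L)),
        BvsA = backgroundTest(byAllele[[alleles[2]]],
                              byAllele[[alleles[1]]], sub1,
                              modelSettings = testSettings,
                              nReps = cfg$randomizations,
                              seed = childSeed(cfg$seed, 601L)))
    }

    stage <- "outputs"
    evalTab <- do.call(rbind, lapply(names(perSet), function(sn)
      do.call(rbind, lapply(alleles, function(al)
        data.frame(set = sn, allele = al,
                   meanAUC = mean(perSet[[sn]][[al]]$auc),
                   minAUC = min(perSet[[sn]][[al]]$auc),
                   maxAUC = max(perSet[[sn]][[al]]$auc),
                   meanPAUC = mean(perSet[[sn]][[al]]$pauc))))))
    utils::write.csv(evalTab, file.path(outdir, "evaluation.csv"),
                     row.names = FALSE)
    areaTab <- data.frame(
      scenario = c("present", names(favFuture)),
      t(vapply(c(list(favPresent), favFuture),
               function(f) f@percents, numeric(2))))
    names(areaTab)[2:3] <- alleles
    utils::write.csv(areaTab, file.path(outdir, "favoured_area.csv"),
                     row.names = FALSE)
    for (al in alleles) {
      writeSurface(set1[[al]]$meanSurface,
                   file.path(outdir, paste0("suitability_", al, ".asc")))
      writeMaxentModel(set1[[al]]$fullFit,
                       file.path(outdir, paste0("model_", al, ".yaml")))
    }
    if (!is.null(idTest))
      writeOverlapResult(idTest, file.path(outdir, "identity_test.yaml"))
    logLine("pipeline complete")

    list(outdir = outdir, config = cfg, occThinned = thinned,
         occByAllele = byAllele, varSets = varSets, perSet = perSet,
         thresholds = thresholds, classified = classified,
         favPresent = favPresent, favFuture = favFuture,
         scenarioSurfaces = scenarioSurfaces, dGeographic = dGeo,
         dEnvironmental = dEnv, identity = idTest,
         background = bgTests, evaluation = evalTab,
         favouredArea = areaTab)
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    logLine("FAILED at stage '%s': %s", stage,
            attr(res, "condition")$message)
    stop("pipeline failed at stage '", stage, "': ",
         attr(res, "condition")$message, call. = FALSE)
  }
  invisible(res)
}

## restrict a stack to a subset of layers (keeps grid and mask)
presentSubStack <- function(stack, vars) {
  missing <- setdiff(vars, layerNames(stack))
  if (length(missing))
    stop("stack lacks variable(s): ", paste(missing, collapse = ", "))
  layers <- lapply(vars, function(v) stack@layers[, , v])
  names(layers) <- vars
  climateStack(layers, xll = stack@xll, yll = stack@yll,
               cellsize = stack@cellsize, nodata = stack@nodata,
               mask = stack@mask)
}
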