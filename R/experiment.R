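## End-to-end experiment driver: simulate -> train -> predict -> evaluate.

#' Simulate a dataset of reconstructed slices with ground-truth TFA maps
#'
#' Each slice draws a fresh background and tumor, projects tumor
#' (high-resolution) and background (PET-resolution) separately, sums the
#' sinograms, applies Poisson noise and reconstructs with OSEM.  Fully
#' reproducible from \code{seed}.
#'
#' @param n number of slices.
#' @param tumorCfg a \code{\linkS4class{TumorConfig}}.
#' @param backgroundParams \code{\linkS4class{LumpyParams}} for backgrounds.
#' @param sys a \code{\linkS4class{SystemModel}}.
#' @param seed integer seed.
#' @param nSubsets,nIterations OSEM settings.
#' @return List with elements \code{images} (list of
#'   \code{\linkS4class{ReconImage}}), \code{tfa} (list of
#'   \code{\linkS4class{TFAMap}}), \code{areasCm2} (true areas) and
#'   \code{seed}.
#' @export
simulateSlices <- function(n, tumorCfg, backgroundParams, sys, seed,
                           nSubsets = 21L, nIterations = 2L) {
  set.seed(seed)
  images <- vector("list", n); tfa <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- samplePhantom(tumorCfg, backgroundParams, sys@imageDim,
                        sys@pixelSizeMm)
    images[[i]] <- simulateSlice(ph, sys, nSubsets = nSubsets,
                                 nIterations = nIterations)
    tfa[[i]] <- computeTFA(ph)
  }
  list(images = images, tfa = tfa,
       areasCm2 = vapply(tfa, tumorArea, numeric(1)), seed = seed)
}

#' Evaluate a trained estimator on a test set
#'
#' Computes the pixel-wise EMSE, the normalized area EMSE, the
#' ensemble-average bias map, mean fuzzy DSC/JSC with Student-t 95% CIs,
#' and the per-area-bin summary.
#'
#' @param estimator a \code{\linkS4class{TrainedEstimator}}.
#' @param images test \code{\linkS4class{ReconImage}}s.
#' @param truths paired ground-truth \code{\linkS4class{TFAMap}}s.
#' @param binWidthCm2 area bin width for the per-bin table.
#' @param nRealizations noise realizations per tumor (metadata for the
#'   bias-map sample counts; the default treats each slice as one tumor).
#' @return An \code{\linkS4class{EvalReport}}; per-slice DSC/JSC vectors
#'   and predictions are kept in \code{@meta}.
#' @export
evaluateEstimator <- function(estimator, images, truths, binWidthCm2 = 2,
                              nRealizations = 1L) {
  pixArea <- truths[[1]]@pixelAreaCm2
  preds <- predictTFABatch(estimator, images, pixArea)
  ov <- vapply(seq_along(preds), function(i)
    dscJsc(fuzzyConfusion(truths[[i]], preds[[i]])), numeric(2))
  dsc <- meanCi95(ov[1, ]); jsc <- meanCi95(ov[2, ])
  P <- length(preds) %/% nRealizations
  new("EvalReport",
      pixelwiseEmse = pixelwiseEMSE(truths, preds),
      normalizedAreaEmse = normalizedAreaEMSE(truths, preds),
      biasMap = ensembleBias(truths, preds, P = P, N = nRealizations),
      dscMeanCi = unname(dsc), jscMeanCi = unname(jsc),
      perBin = areaRatioStudy(truths, preds, binWidthCm2),
      nTumors = as.integer(P), nRealizations = as.integer(nRealizations),
      meta = list(dsc = ov[1, ], jsc = ov[2, ], predictions = preds))
}

#' Run a full simulation experiment
#'
#' Simulates disjoint training and test sets (distinct tumors and
#' backgrounds via disjoint seed streams), trains the TFA estimator, and
#' evaluates it on the held-out set.  A pure function of its configuration
#' and seed.
#'
#' @param nTrain,nTest sample sizes (both >= 1).
#' @param tumorCfg,backgroundParams,sys simulation configuration.
#' @param netCfg,trainCfg estimator configuration.
#' @param seed master seed; training/test simulation and network training
#'   derive distinct seeds from it.
#' @param outDir optional directory: when given, the dataset, predictions
#'   and report are persisted there.
#' @return A list: \code{report} (\code{\linkS4class{EvalReport}}),
#'   \code{estimator}, \code{train}, \code{test} (the simulated sets).
#' @export
runExperiment <- function(nTrain, nTest, tumorCfg, backgroundParams, sys,
                          netCfg, trainCfg, seed = 1L, outDir = NULL) {
  if (nTrain < 1L || nTest < 1L) stop("nTrain and nTest must be >= 1")
  seeds <- deriveSeeds(seed, 3L)
  trainSet <- simulateSlices(nTrain, tumorCfg, backgroundParams, sys,
                             seed = seeds[1])
  testSet <- simulateSlices(nTest, tumorCfg, backgroundParams, sys,
                            seed = seeds[2])
  trainCfg@seed <- seeds[3]
  estimator <- trainEstimator(trainSet$images, trainSet$tfa, netCfg,
                              trainCfg)
  report <- evaluateEstimator(estimator, testSet$images, testSet$tfa)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeDataset(testSet, file.path(outDir, "test"))
    writeDataset(trainSet, file.path(outDir, "train"))
    saveEstimator(estimator, file.path(outDir, "estimator.json"))
    writeReport(report, file.path(outDir, "report.json"))
  }
  list(report = report, estimator = estimator, train = trainSet,
       test = testSet)
}

## Derive k child seeds from a master seed (distinct, < 2^31).
deriveSeeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max, k)
}

#' Structured experiment configuration
#'
#' A single serializable description of a full experiment: phantom
#' population, system model, network, training options and evaluation
#' options.  \code{saveConfig}/\code{loadConfig} round-trip it losslessly
#' through JSON, and \code{runConfiguredExperiment} executes it.
#'
#' @param imageDim,pixelSizeMm,fwhmMm,nAngles,countScale,gridRatio system
#'   geometry (see \code{\link{systemModel}}).
#' @param areaRangeCm2,tbrRange tumor population (see
#'   \code{\link{tumorConfig}}).
#' @param depth,baseChannels,learningRate,batchSize,epochs estimator
#'   settings.
#' @param binWidthCm2 evaluation area-bin width.
#' @param seed master seed.
#' @return A named list of class \code{"tfasegConfig"}.
#' @export
experimentConfig <- function(imageDim = 64L, pixelSizeMm = 4.07,
                             fwhmMm = 5, nAngles = 84L, countScale = 5e5,
                             gridRatio = 8L, areaRangeCm2 = c(1, 9),
                             tbrRange = c(2, 8), depth = 3L,
                             baseChannels = 8L, learningRate = 1e-3,
                             batchSize = 10L, epochs = 35L,
                             binWidthCm2 = 2, seed = 1L) {
  cfg <- list(imageDim = as.integer(imageDim),
              pixelSizeMm = as.numeric(pixelSizeMm),
              fwhmMm = as.numeric(fwhmMm), nAngles = as.integer(nAngles),
              countScale = as.numeric(countScale),
              gridRatio = as.integer(gridRatio),
              areaRangeCm2 = as.numeric(areaRangeCm2),
              tbrRange = as.numeric(tbrRange), depth = as.integer(depth),
              baseChannels = as.integer(baseChannels),
              learningRate = as.numeric(learningRate),
              batchSize = as.integer(batchSize),
              epochs = as.integer(epochs),
              binWidthCm2 = as.numeric(binWidthCm2), seed = as.integer(seed))
  class(cfg) <- "tfasegConfig"
  cfg
}

#' @rdname experimentConfig
#' @param cfg a configuration from \code{experimentConfig}.
#' @param path file path for the JSON configuration.
#' @export
saveConfig <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname experimentConfig
#' @export
loadConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(experimentConfig, raw)
}

#' @rdname experimentConfig
#' @param nTrain,nTest sample sizes.
#' @export
runConfiguredExperiment <- function(cfg, nTrain, nTest) {
  stopifnot(inherits(cfg, "tfasegConfig"))
  sys <- systemModel(cfg$imageDim, cfg$pixelSizeMm, cfg$fwhmMm,
                     nAngles = cfg$nAngles, countScale = cfg$countScale,
                     gridRatio = cfg$gridRatio)
  tc <- tumorConfig(areaRangeCm2 = cfg$areaRangeCm2,
                    tbrRange = cfg$tbrRange, gridRatio = cfg$gridRatio)
  runExperiment(nTrain, nTest, tc, lumpyParams(6, c(15, 40), c(0.2, 0.6)),
                sys, networkConfig(cfg$imageDim, cfg$depth,
                                   cfg$baseChannels),
                trainingConfig(learningRate = cfg$learningRate,
                               batchSize = cfg$batchSize,
                               epochs = cfg$epochs),
                seed = cfg$seed)
}

#' Run the scaled-down simulation study
#'
#' The package's headline experiment at desk scale: 64 x 64 slices with
#' 4.07 mm pixels and a 5 mm FWHM system (clinical FWHM-to-pixel ratio),
#' tumors drawn at grid ratio 8, OSEM with 21 subsets and 2 iterations,
#' an encoder-decoder of depth 3 with 8 base channels trained for 35
#' epochs on \code{nTrain} slices, and evaluation on \code{nTest}
#' independent slices.
#'
#' @param seed master seed.
#' @param nTrain,nTest training and held-out sample sizes.
#' @param classifier also train the classification-network baseline and
#'   attach its binarized predictions and per-bin summary to the result.
#' @param epochs training epochs.
#' @return The \code{\link{runExperiment}} result list, with
#'   \code{classifierPerBin} and \code{classifierMasks} added when
#'   \code{classifier = TRUE}.
#' @export
runScaledStudy <- function(seed = 1L, nTrain = 500L, nTest = 100L,
                           classifier = FALSE, epochs = 35L) {
  sys <- systemModel(64, pixelSizeMm = 4.07, fwhmMm = 5, nAngles = 84,
                     countScale = 5e5, gridRatio = 8L)
  tumorCfg <- tumorConfig()                 # grid ratio 8, 1-9 cm^2
  bgParams <- lumpyParams(6, c(15, 40), c(0.2, 0.6))
  netCfg <- networkConfig(64, depth = 3, baseChannels = 8)
  trainCfg <- trainingConfig(learningRate = 1e-3, batchSize = 10L,
                             epochs = as.integer(epochs))
  res <- runExperiment(nTrain, nTest, tumorCfg, bgParams, sys, netCfg,
                       trainCfg, seed = seed)
  res$system <- sys
  if (classifier) {
    trainCfg@seed <- deriveSeeds(seed, 4L)[4]
    clf <- classificationBaselineTrain(res$train$images, res$train$tfa,
                                       netCfg, trainCfg)
    pixArea <- res$test$tfa[[1]]@pixelAreaCm2
    masks <- lapply(predictTFABatch(clf, res$test$images, pixArea),
                    function(m) tfaMap(binarizeTFA(m, 0.5), pixArea))
    res$classifier <- clf
    res$classifierMasks <- masks
    res$classifierPerBin <- areaRatioStudy(res$test$tfa, masks)
  }
  res
}
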