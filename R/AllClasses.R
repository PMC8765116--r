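#' @import methods
#' @importFrom Matrix sparseMatrix t colSums rowSums
#' @importFrom stats rnorm rpois runif qt t.test dnorm convolve quantile
#' @importFrom utils head tail
NULL

## ---------------------------------------------------------------------------
## Phantom-side configuration classes
## ---------------------------------------------------------------------------

#' Parameters of a stochastic lumpy object model
#'
#' A lumpy field is a sum of a Poisson-distributed number of isotropic
#' Gaussian "lumps" with random centers, widths and amplitudes.  It is used
#' both to draw tumor supports (by thresholding the field) and to texture
#' tumor interiors and backgrounds.
#'
#' @slot meanNumLumps Poisson mean of the number of lumps.
#' @slot lumpWidthRange ordered pair (mm): range of the Gaussian lump
#'   standard deviation.
#' @slot lumpAmplitudeRange ordered pair: range of lump amplitudes
#'   (arbitrary activity units).
#' @export
setClass("LumpyParams",
  representation(meanNumLumps = "numeric",
                 lumpWidthRange = "numeric",
                 lumpAmplitudeRange = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@meanNumLumps) != 1L || object@meanNumLumps <= 0)
      msg <- c(msg, "meanNumLumps must be a single positive number")
    for (nm in c("lumpWidthRange", "lumpAmplitudeRange")) {
      r <- slot(object, nm)
      if (length(r) != 2L || any(r <= 0) || r[1] > r[2])
        msg <- c(msg, paste0(nm, " must be an ordered positive pair"))
    }
    if (is.null(msg)) TRUE else msg
  })

#' @rdname LumpyParams-class
#' @param meanNumLumps,lumpWidthRange,lumpAmplitudeRange see slots.
#' @return A \code{LumpyParams} object.
#' @examples
#' lumpyParams(10, c(4, 12), c(0.5, 1))
#' @export
lumpyParams <- function(meanNumLumps, lumpWidthRange, lumpAmplitudeRange) {
  new("LumpyParams", meanNumLumps = as.numeric(meanNumLumps),
      lumpWidthRange = as.numeric(lumpWidthRange),
      lumpAmplitudeRange = as.numeric(lumpAmplitudeRange))
}

#' Configuration of the simulated tumor population
#'
#' Holds the sampled tumor property distributions: target cross-section
#' area (uniform over \code{areaRangeCm2}), tumor-to-background mean
#' intensity ratio (uniform over \code{tbrRange}), the lumpy model that
#' generates tumor shapes (\code{supportLumpy}) and the one that generates
#' intra-tumor heterogeneity (\code{textureLumpy}), and the ratio of the
#' high-resolution tumor grid to the PET grid.
#'
#' @slot areaRangeCm2 ordered pair (cm^2).
#' @slot tbrRange ordered pair of reals > 1.
#' @slot supportLumpy,textureLumpy \code{LumpyParams}.
#' @slot gridRatio integer >= 2, high-res pixels per PET pixel per axis.
#' @export
setClass("TumorConfig",
  representation(areaRangeCm2 = "numeric", tbrRange = "numeric",
                 supportLumpy = "LumpyParams", textureLumpy = "LumpyParams",
                 gridRatio = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@areaRangeCm2) != 2L || any(object@areaRangeCm2 <= 0) ||
        object@areaRangeCm2[1] > object@areaRangeCm2[2])
      msg <- c(msg, "areaRangeCm2 must be an ordered positive pair")
    if (length(object@tbrRange) != 2L || any(object@tbrRange <= 1) ||
        object@tbrRange[1] > object@tbrRange[2])
      msg <- c(msg, "tbrRange must be an ordered pair with min > 1")
    if (object@gridRatio < 2L)
      msg <- c(msg, "gridRatio must be >= 2")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname TumorConfig-class
#' @param areaRangeCm2,tbrRange,supportLumpy,textureLumpy,gridRatio see slots.
#' @details Defaults describe the lung-tumor population emulated by the
#'   simulation study: cross-sections of 1 to 9 cm^2 and tumor-to-background
#'   ratios of 2 to 8 relative to the soft-tissue background mean.
#' @return A \code{TumorConfig} object.
#' @export
tumorConfig <- function(areaRangeCm2 = c(1, 9), tbrRange = c(2, 8),
                        supportLumpy = lumpyParams(8, c(3, 9), c(0.5, 1)),
                        textureLumpy = lumpyParams(10, c(3, 8), c(0.3, 1)),
                        gridRatio = 8L) {
  new("TumorConfig", areaRangeCm2 = as.numeric(areaRangeCm2),
      tbrRange = as.numeric(tbrRange), supportLumpy = supportLumpy,
      textureLumpy = textureLumpy, gridRatio = as.integer(gridRatio))
}

#' High-resolution phantom: tumor support and activities
#'
#' The simulated tracer distribution f(r) = f_b(r) + f_s(r): the tumor
#' support s(r) and tumor activity f_s(r) live on a fine grid
#' (\code{gridRatio} times the PET grid per axis), the background activity
#' f_b(r) on the PET grid.
#'
#' @slot support binary matrix, (imageDim * gridRatio)^2.
#' @slot tumorActivity nonnegative matrix, same shape as \code{support};
#'   positive exactly where \code{support == 1}.
#' @slot backgroundActivity nonnegative matrix, imageDim^2.
#' @slot pixelSizeMm PET pixel size (mm).
#' @slot gridRatio integer.
#' @export
setClass("HighResPhantom",
  representation(support = "matrix", tumorActivity = "matrix",
                 backgroundActivity = "matrix", pixelSizeMm = "numeric",
                 gridRatio = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!all(object@support %in% c(0, 1)))
      msg <- c(msg, "support must be binary")
    if (!identical(dim(object@support), dim(object@tumorActivity)))
      msg <- c(msg, "support and tumorActivity dims differ")
    if (any(object@tumorActivity < 0) || any(object@backgroundActivity < 0))
      msg <- c(msg, "activities must be nonnegative")
    if (!all(dim(object@support) ==
             dim(object@backgroundActivity) * object@gridRatio))
      msg <- c(msg, "support grid must be gridRatio times the PET grid")
    if (any((object@tumorActivity > 0) != (object@support == 1)))
      msg <- c(msg, "tumorActivity must be positive exactly on the support")
    if (is.null(msg)) TRUE else msg
  })

## ---------------------------------------------------------------------------
## Imaging-side classes
## ---------------------------------------------------------------------------

#' PET system model
#'
#' Embodies the linear forward operator H (image-domain Gaussian blur of the
#' stated FWHM followed by parallel-beam line integrals), the Poisson noise
#' level, and the geometry shared by projection and OSEM reconstruction.
#' The geometric projector is precomputed as a sparse matrix
#' (pixel-driven, linear detector-bin interpolation), so its adjoint is the
#' exact matrix transpose.
#'
#' @slot fwhmMm system resolution, full width at half maximum (mm).
#' @slot imageDim PET grid side length (pixels).
#' @slot pixelSizeMm PET pixel size (mm); also the detector bin size.
#' @slot nAngles projection angles over 180 degrees.
#' @slot countScale expected total detected counts per slice.
#' @slot gridRatio high-resolution grid ratio used by the phantom path.
#' @slot projector sparse geometric projection matrix,
#'   (nAngles * nBins) x imageDim^2.
#' @export
setClass("SystemModel",
  representation(fwhmMm = "numeric", imageDim = "integer",
                 pixelSizeMm = "numeric", nAngles = "integer",
                 countScale = "numeric", gridRatio = "integer",
                 projector = "ANY"),
  validity = function(object) {
    msg <- NULL
    if (object@fwhmMm <= 0) msg <- c(msg, "fwhmMm must be positive")
    if (object@countScale <= 0) msg <- c(msg, "countScale must be positive")
    if (object@nAngles < object@imageDim)
      msg <- c(msg, "nAngles must be >= imageDim (angular sampling adequacy)")
    if (is.null(msg)) TRUE else msg
  })

#' Projection-domain data
#'
#' @slot values nonnegative matrix, nAngles x nBins.
#' @slot binSizeMm detector bin size (mm).
#' @slot meta list of provenance fields (e.g. noise scale factor, seed).
#' @export
setClass("Sinogram",
  representation(values = "matrix", binSizeMm = "numeric", meta = "list"),
  validity = function(object) {
    if (any(object@values < 0)) "sinogram values must be nonnegative" else TRUE
  })

#' Reconstructed PET image
#'
#' @slot values nonnegative matrix, imageDim^2.
#' @slot pixelSizeMm pixel size (mm).
#' @slot meta provenance (iterations, subsets, seed, ...).
#' @export
setClass("ReconImage",
  representation(values = "matrix", pixelSizeMm = "numeric", meta = "list"),
  validity = function(object) {
    msg <- NULL
    if (any(object@values < 0)) msg <- c(msg, "values must be nonnegative")
    if (object@pixelSizeMm <= 0) msg <- c(msg, "pixelSizeMm must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname ReconImage-class
#' @param values,pixelSizeMm,meta see slots.
#' @return A \code{ReconImage}.
#' @export
reconImage <- function(values, pixelSizeMm, meta = list()) {
  new("ReconImage", values = values, pixelSizeMm = as.numeric(pixelSizeMm),
      meta = meta)
}

## ---------------------------------------------------------------------------
## TFA map
## ---------------------------------------------------------------------------

#' Tumor-fraction area map
#'
#' Per-PET-pixel fraction of the pixel area occupied by tumor, in [0, 1]:
#' the ground-truth vector a, or its estimate.
#'
#' @slot values matrix with entries in [0, 1].
#' @slot pixelAreaCm2 area of one PET pixel (cm^2).
#' @export
setClass("TFAMap",
  representation(values = "matrix", pixelAreaCm2 = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(object@values < 0) || any(object@values > 1))
      msg <- c(msg, "TFA values must lie in [0, 1]")
    if (object@pixelAreaCm2 <= 0)
      msg <- c(msg, "pixelAreaCm2 must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname TFAMap-class
#' @param values,pixelAreaCm2 see slots.
#' @return A \code{TFAMap}.
#' @export
tfaMap <- function(values, pixelAreaCm2) {
  new("TFAMap", values = values, pixelAreaCm2 = as.numeric(pixelAreaCm2))
}

## ---------------------------------------------------------------------------
## Estimator-side classes
## ---------------------------------------------------------------------------

#' Encoder-decoder network configuration
#'
#' The contracting path halves the spatial dimensions \code{depth} times
#' while doubling channels; the expansive path mirrors it, with skip
#' connections added element-wise; a final 1x1 convolution with a logistic
#' squash maps to (0, 1).
#'
#' @slot depth number of resolution halvings (>= 2 encoder levels).
#' @slot baseChannels channels at the first level.
#' @slot kernelSize convolution kernel size (fixed 3).
#' @slot inputDim input side length; must be divisible by 2^depth.
#' @export
setClass("NetworkConfig",
  representation(depth = "integer", baseChannels = "integer",
                 kernelSize = "integer", inputDim = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@depth < 2L) msg <- c(msg, "depth must be >= 2")
    if (object@inputDim %% (2L^object@depth) != 0L)
      msg <- c(msg, "inputDim must be divisible by 2^depth")
    if (object@kernelSize != 3L) msg <- c(msg, "kernelSize is fixed at 3")
    if (object@baseChannels < 1L) msg <- c(msg, "baseChannels must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname NetworkConfig-class
#' @param inputDim,depth,baseChannels,kernelSize see slots.
#' @return A \code{NetworkConfig}.
#' @export
networkConfig <- function(inputDim, depth = 3L, baseChannels = 32L,
                          kernelSize = 3L) {
  new("NetworkConfig", depth = as.integer(depth),
      baseChannels = as.integer(baseChannels),
      kernelSize = as.integer(kernelSize), inputDim = as.integer(inputDim))
}

#' Training configuration
#'
#' @slot learningRate Adam step size.
#' @slot batchSize minibatch size.
#' @slot epochs training epochs.
#' @slot nFolds folds for cross-validation (default 5).
#' @slot seed integer seed controlling initialization and shuffling.
#' @slot clampEps floor applied to log arguments in the BCE cost.
#' @export
setClass("TrainingConfig",
  representation(learningRate = "numeric", batchSize = "integer",
                 epochs = "integer", nFolds = "integer", seed = "integer",
                 clampEps = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@clampEps <= 0 || object@clampEps >= 0.5)
      msg <- c(msg, "clampEps must be in (0, 0.5)")
    if (object@nFolds < 2L) msg <- c(msg, "nFolds must be >= 2")
    if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
    if (object@epochs < 1L || object@batchSize < 1L)
      msg <- c(msg, "epochs and batchSize must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname TrainingConfig-class
#' @param learningRate,batchSize,epochs,nFolds,seed,clampEps see slots.
#' @return A \code{TrainingConfig}.
#' @export
trainingConfig <- function(learningRate = 1e-3, batchSize = 10L,
                           epochs = 30L, nFolds = 5L, seed = 1L,
                           clampEps = 1e-7) {
  new("TrainingConfig", learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      nFolds = as.integer(nFolds), seed = as.integer(seed),
      clampEps = as.numeric(clampEps))
}

#' A trained TFA estimator
#'
#' @slot weights list of parameter matrices (convolution kernels and biases).
#' @slot config the \code{NetworkConfig} used.
#' @slot history numeric vector of per-epoch mean training cost.
#' @slot meta list (seed, training options, input normalization rule).
#' @export
setClass("TrainedEstimator",
  representation(weights = "list", config = "NetworkConfig",
                 history = "numeric", meta = "list"))

#' Scalar toy observation model with tractable posterior
#'
#' Observation = v + Gaussian noise with v in [0, 1] drawn from a named
#' prior; used to verify numerically that BCE training recovers the
#' posterior mean.
#'
#' @slot prior one of "uniform", "beta", "two_point".
#' @slot priorParams numeric parameters (beta: shape1, shape2; two_point:
#'   the two support points followed by the probability of the first).
#' @slot noiseSigma Gaussian observation noise sd (> 0).
#' @slot quadratureN quadrature nodes (>= 128).
#' @export
setClass("ToyPosteriorModel",
  representation(prior = "character", priorParams = "numeric",
                 noiseSigma = "numeric", quadratureN = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@prior %in% c("uniform", "beta", "two_point"))
      msg <- c(msg, "prior must be uniform, beta or two_point")
    if (object@noiseSigma <= 0) msg <- c(msg, "noiseSigma must be > 0")
    if (object@quadratureN < 128L) msg <- c(msg, "quadratureN must be >= 128")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname ToyPosteriorModel-class
#' @param prior,priorParams,noiseSigma,quadratureN see slots.
#' @return A \code{ToyPosteriorModel}.
#' @export
toyPosteriorModel <- function(prior = "uniform", priorParams = numeric(0),
                              noiseSigma = 0.1, quadratureN = 2048L) {
  new("ToyPosteriorModel", prior = prior,
      priorParams = as.numeric(priorParams),
      noiseSigma = as.numeric(noiseSigma),
      quadratureN = as.integer(quadratureN))
}

## ---------------------------------------------------------------------------
## Evaluation classes
## ---------------------------------------------------------------------------

#' Fuzzy confusion cardinalities
#'
#' True/false positives/negatives generalized to [0,1]-valued membership
#' maps via per-pixel min/max.
#'
#' @slot tp,fp,tn,fn nonnegative reals.
#' @slot nPixels total pixel count M; tp+fp+tn+fn == M identically.
#' @export
setClass("FuzzyConfusion",
  representation(tp = "numeric", fp = "numeric", tn = "numeric",
                 fn = "numeric", nPixels = "numeric"),
  validity = function(object) {
    if (any(c(object@tp, object@fp, object@tn, object@fn) < -1e-9))
      "cardinalities must be nonnegative" else TRUE
  })

#' Evaluation report
#'
#' @slot pixelwiseEmse empirical pixel-wise ensemble mean squared error.
#' @slot normalizedAreaEmse mean of |Ahat - A|^2 / A^2.
#' @slot biasMap per-pixel ensemble-average bias matrix.
#' @slot dscMeanCi,jscMeanCi numeric triples (mean, ci_low, ci_high).
#' @slot perBin data.frame of per-area-bin summaries.
#' @slot nTumors,nRealizations sample-count metadata (P and N).
#' @slot meta list of extra fields (per-slice metric vectors, config echo).
#' @export
setClass("EvalReport",
  representation(pixelwiseEmse = "numeric", normalizedAreaEmse = "numeric",
                 biasMap = "matrix", dscMeanCi = "numeric",
                 jscMeanCi = "numeric", perBin = "data.frame",
                 nTumors = "integer", nRealizations = "integer",
                 meta = "list"))
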