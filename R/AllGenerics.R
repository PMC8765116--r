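#' Extract the numeric grid from a container
#'
#' @param x a \code{Sinogram}, \code{ReconImage}, \code{TFAMap} or
#'   \code{HighResPhantom} (returns the support for the latter).
#' @return A numeric matrix.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname values
#' @export
setMethod("values", "Sinogram", function(x) x@values)
#' @rdname values
#' @export
setMethod("values", "ReconImage", function(x) x@values)
#' @rdname values
#' @export
setMethod("values", "TFAMap", function(x) x@values)
#' @rdname values
#' @export
setMethod("values", "HighResPhantom", function(x) x@support)

#' Pixel size accessor (mm)
#'
#' @param x an object with a pixel size.
#' @return Pixel size in mm.
#' @export
setGeneric("pixelSizeMm", function(x) standardGeneric("pixelSizeMm"))
#' @rdname pixelSizeMm
#' @export
setMethod("pixelSizeMm", "ReconImage", function(x) x@pixelSizeMm)
#' @rdname pixelSizeMm
#' @export
setMethod("pixelSizeMm", "SystemModel", function(x) x@pixelSizeMm)
#' @rdname pixelSizeMm
#' @export
setMethod("pixelSizeMm", "HighResPhantom", function(x) x@pixelSizeMm)

setMethod("show", "LumpyParams", function(object) {
  cat("LumpyParams: E[#lumps] =", object@meanNumLumps,
      "| width", paste(object@lumpWidthRange, collapse = "-"), "mm",
      "| amplitude", paste(object@lumpAmplitudeRange, collapse = "-"), "\n")
})

setMethod("show", "TumorConfig", function(object) {
  cat("TumorConfig: area", paste(object@areaRangeCm2, collapse = "-"),
      "cm^2 | TBR", paste(object@tbrRange, collapse = "-"),
      "| grid ratio", object@gridRatio, "\n")
})

setMethod("show", "SystemModel", function(object) {
  cat(sprintf(paste0("SystemModel: %dx%d grid, %.3g mm pixels, ",
                     "FWHM %.3g mm, %d angles, %.3g counts\n"),
              object@imageDim, object@imageDim, object@pixelSizeMm,
              object@fwhmMm, object@nAngles, object@countScale))
})

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram: %d angles x %d bins (%.3g mm), total %.4g\n",
              nrow(object@values), ncol(object@values), object@binSizeMm,
              sum(object@values)))
})

setMethod("show", "ReconImage", function(object) {
  v <- object@values
  cat(sprintf("ReconImage: %dx%d, %.3g mm pixels, range [%.3g, %.3g]\n",
              nrow(v), ncol(v), object@pixelSizeMm, min(v), max(v)))
})

setMethod("show", "TFAMap", function(object) {
  cat(sprintf("TFAMap: %dx%d, pixel %.4g cm^2, tumor area %.4g cm^2\n",
              nrow(object@values), ncol(object@values),
              object@pixelAreaCm2, tumorArea(object)))
})

setMethod("show", "HighResPhantom", function(object) {
  cat(sprintf(paste0("HighResPhantom: support %dx%d (ratio %d), ",
                     "tumor area %.4g cm^2\n"),
              nrow(object@support), ncol(object@support), object@gridRatio,
              sum(object@support) *
                (object@pixelSizeMm / object@gridRatio / 10)^2))
})

setMethod("show", "FuzzyConfusion", function(object) {
  cat(sprintf("FuzzyConfusion: TP %.4g FP %.4g TN %.4g FN %.4g (M = %g)\n",
              object@tp, object@fp, object@tn, object@fn, object@nPixels))
})

setMethod("show", "TrainedEstimator", function(object) {
  cat(sprintf(paste0("TrainedEstimator: input %dx%d, depth %d, base %d ",
                     "channels, %d epochs (final cost %.4g)\n"),
              object@config@inputDim, object@config@inputDim,
              object@config@depth, object@config@baseChannels,
              length(object@history),
              if (length(object@history)) tail(object@history, 1) else NA))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  cat(sprintf("  pixel-wise EMSE:      %.4g\n", object@pixelwiseEmse))
  cat(sprintf("  normalized area EMSE: %.4g\n", object@normalizedAreaEmse))
  cat(sprintf("  DSC: %.3f (95%% CI %.3f, %.3f)\n", object@dscMeanCi[1],
              object@dscMeanCi[2], object@dscMeanCi[3]))
  cat(sprintf("  JSC: %.3f (95%% CI %.3f, %.3f)\n", object@jscMeanCi[1],
              object@jscMeanCi[2], object@jscMeanCi[3]))
  cat(sprintf("  bias map range: [%.3g, %.3g]\n", min(object@biasMap),
              max(object@biasMap)))
  cat(sprintf("  samples: %d tumors x %d realizations\n", object@nTumors,
              object@nRealizations))
  if (nrow(object@perBin)) {
    cat("  per-area-bin summary:\n")
    print(object@perBin, row.names = FALSE)
  }
})
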