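## Comparison methods and the PVE-sensitivity machinery: 40% SUV-max
## thresholding, a classification-trained network baseline (same
## architecture, binary targets), boxcar-degraded "PVE-affected" masks, and
## area-binned ratio reporting.

#' Rectangular region of interest on the PET grid
#'
#' @param rowRange,colRange integer ranges (inclusive).
#' @param imageDim grid side, for bounds checking.
#' @return A list with validated \code{rows} and \code{cols} sequences.
#' @export
roiBox <- function(rowRange, colRange, imageDim) {
  if (rowRange[1] > rowRange[2] || colRange[1] > colRange[2] ||
      rowRange[1] < 1 || colRange[1] < 1 ||
      rowRange[2] > imageDim || colRange[2] > imageDim)
    stop("ROI out of bounds or empty")
  list(rows = rowRange[1]:rowRange[2], cols = colRange[1]:colRange[2])
}

## Truth bounding box padded by `pad` pixels; stands in for a manually
## drawn ROI in simulation mode.
autoRoi <- function(truthMap, pad = 4L) {
  v <- if (is(truthMap, "TFAMap")) truthMap@values else truthMap
  idx <- which(v > 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty truth map: no ROI")
  n <- nrow(v)
  roiBox(c(max(1L, min(idx[, 1]) - pad), min(n, max(idx[, 1]) + pad)),
         c(max(1L, min(idx[, 2]) - pad), min(n, max(idx[, 2]) + pad)), n)
}

#' SUV-max fractional thresholding
#'
#' Within the ROI, selects pixels at or above \code{fraction} times the ROI
#' maximum and keeps the largest connected component; everything outside
#' the ROI is zero.
#'
#' @param image a \code{\linkS4class{ReconImage}} or matrix.
#' @param roi an ROI from \code{\link{roiBox}}.
#' @param fraction threshold fraction of the ROI maximum (default 0.40).
#' @return Binary matrix the size of the image.
#' @export
suvmaxThreshold <- function(image, roi, fraction = 0.40) {
  v <- if (is(image, "ReconImage")) image@values else image
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  sub <- v[roi$rows, roi$cols, drop = FALSE]
  mask <- largestComponent(sub >= fraction * max(sub))
  out <- matrix(0, nrow(v), ncol(v))
  out[roi$rows, roi$cols] <- mask
  out
}

#' Train the classification-network baseline
#'
#' Same architecture and optimizer as the TFA estimator, but the training
#' targets are binary tumor masks (each pixel assigned wholly to tumor or
#' background), as in conventional segmentation networks.  Ground truth is
#' the TFA map binarized at 0.5.
#'
#' @param images list of \code{\linkS4class{ReconImage}}s.
#' @param tfaMaps paired ground-truth \code{\linkS4class{TFAMap}}s (will be
#'   binarized), or already-binary matrices.
#' @param netCfg,trainCfg as in \code{\link{trainEstimator}}.
#' @return A \code{\linkS4class{TrainedEstimator}} whose raw output is a
#'   classification probability map (not a TFA map); binarize its output at
#'   0.5 for segmentation.
#' @export
classificationBaselineTrain <- function(images, tfaMaps, netCfg, trainCfg) {
  masks <- lapply(tfaMaps, function(m) {
    if (is(m, "TFAMap")) binarizeTFA(m, 0.5)
    else if (all(m %in% c(0, 1))) m
    else (m >= 0.5) * 1
  })
  est <- trainEstimator(images, masks, netCfg, trainCfg)
  est@meta$kind <- "classification"
  est
}

#' PVE-affected version of a ground-truth TFA map
#'
#' Convolves the truth map with a width^2 rectangular (boxcar) filter with
#' reflected boundaries, emulating the resolution degradation introduced by
#' forward projection and reconstruction.
#'
#' @param truthMap a \code{\linkS4class{TFAMap}}.
#' @param filterWidthPx odd filter width in pixels (width 1 = identity).
#' @return A \code{\linkS4class{TFAMap}} (values remain in [0, 1]).
#' @export
pveAffectedMask <- function(truthMap, filterWidthPx) {
  stopifnot(is(truthMap, "TFAMap"))
  w <- as.integer(filterWidthPx)
  if (w < 1L || w %% 2L == 0L) stop("filter width must be odd and >= 1")
  v <- boxcar(truthMap@values, w)
  tfaMap(pmin(pmax(v, 0), 1), truthMap@pixelAreaCm2)
}

#' Binary PVE-affected tumor mask
#'
#' Binarizes the boxcar-degraded truth map at a fraction of its maximum
#' (default 40%, mirroring the SUV-max thresholding convention).  Because
#' the filter spreads the tumor beyond its true boundary, the resulting
#' mask overestimates the tumor area, most strongly for small tumors.
#'
#' @param truthMap a \code{\linkS4class{TFAMap}} (ground truth).
#' @param filterWidthPx odd boxcar width in pixels.
#' @param fraction threshold as a fraction of the filtered map's maximum.
#' @return A binary \code{\linkS4class{TFAMap}}.
#' @export
pveBinaryMask <- function(truthMap, filterWidthPx, fraction = 0.40) {
  b <- pveAffectedMask(truthMap, filterWidthPx)
  thr <- fraction * max(b@values)
  if (thr <= 0) stop("empty truth map")
  tfaMap((b@values >= thr) * 1, truthMap@pixelAreaCm2)
}

## Smallest odd integer spanning the system FWHM, in PET pixels.
defaultPveFilterWidth <- function(sys) {
  w <- ceiling(sys@fwhmMm / sys@pixelSizeMm)
  as.integer(if (w %% 2 == 0) w + 1 else max(w, 1))
}

#' Area-binned sensitivity summary
#'
#' Bins test slices by true tumor area (bin width 2 cm^2 by default) and
#' reports, per bin, the mean and 95% CI of the measured-to-true area
#' ratio plus mean fuzzy DSC/JSC of the measured maps.  A ratio of unity
#' indicates insensitivity to partial-volume effects.
#'
#' @param truths list of ground-truth \code{\linkS4class{TFAMap}}s.
#' @param measured paired list of measured maps (estimator output,
#'   PVE-affected truth, or a baseline mask as a \code{TFAMap}).
#' @param binWidthCm2 bin width (default 2).
#' @return data.frame with one row per nonempty bin: \code{binLow},
#'   \code{binHigh}, \code{n}, \code{ratioMean}, \code{ratioCiLow},
#'   \code{ratioCiHigh}, \code{dscMean}, \code{jscMean}.
#' @export
areaRatioStudy <- function(truths, measured, binWidthCm2 = 2) {
  p <- checkPaired(truths, measured)
  aTrue <- vapply(truths, tumorArea, numeric(1))
  aMeas <- vapply(measured, tumorArea, numeric(1))
  if (any(aTrue <= 0)) stop("true areas must be positive")
  ratio <- aMeas / aTrue
  ov <- vapply(seq_along(truths), function(i)
    dscJsc(fuzzyConfusion(truths[[i]], measured[[i]])), numeric(2))
  bin <- floor(aTrue / binWidthCm2)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    i <- which(bin == b)
    ci <- if (length(i) >= 2L) meanCi95(ratio[i])
          else c(ratio[i], NA_real_, NA_real_)
    data.frame(binLow = b * binWidthCm2, binHigh = (b + 1) * binWidthCm2,
               n = length(i), ratioMean = ci[[1]], ratioCiLow = ci[[2]],
               ratioCiHigh = ci[[3]], dscMean = mean(ov[1, i]),
               jscMean = mean(ov[2, i]))
  }))
  rownames(out) <- NULL
  out
}
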