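## Phantom generation: stochastic lumpy tumors on synthetic heterogeneous
## backgrounds, at a high-resolution grid for the tumor (gridRatio x the PET
## grid per axis) so that the tumor boundary is effectively continuous
## relative to the PET pixel size.

## Draw lump centers clustered around `center` (pixel coords).  The first
## lump sits at the center so the support is anchored; later lumps scatter
## with sd `scatterPx`, producing connected blob-like level sets.
drawLumps <- function(params, center, scatterPx, pxSizeMm) {
  n <- rpois(1L, params@meanNumLumps)
  if (n == 0L)
    return(list(centers = matrix(0, 0, 2), widths = numeric(0),
                amps = numeric(0)))
  centers <- cbind(center[1] + c(0, rnorm(n - 1L, sd = scatterPx)),
                   center[2] + c(0, rnorm(n - 1L, sd = scatterPx)))
  widths <- runif(n, params@lumpWidthRange[1], params@lumpWidthRange[2]) /
    pxSizeMm
  amps <- runif(n, params@lumpAmplitudeRange[1], params@lumpAmplitudeRange[2])
  list(centers = centers, widths = widths, amps = amps)
}

#' Sample a high-resolution tumor support
#'
#' Draws a connected tumor support on the high-resolution grid by
#' thresholding a sum of randomly placed Gaussian lumps.  The threshold is
#' chosen (by rank selection on the field values) so that the largest
#' connected component of the thresholded field hits a target area sampled
#' uniformly from \code{areaRangeCm2}; draws whose component area falls
#' outside the range are rejected and redrawn.
#'
#' @param cfg a \code{\linkS4class{TumorConfig}}.
#' @param imageDim PET grid side length.
#' @param pixelSizeMm PET pixel size in mm.
#' @param center tumor center in PET pixel coordinates (row, col);
#'   default the grid center.
#' @param maxAttempts rejection-sampling budget.
#' @return Binary matrix of size \code{(imageDim * gridRatio)^2}.
#' @examples
#' set.seed(1)
#' s <- sampleTumorSupport(tumorConfig(), imageDim = 32, pixelSizeMm = 4.07)
#' sum(s) * (4.07 / 8 / 10)^2   # measured area, cm^2
#' @export
sampleTumorSupport <- function(cfg, imageDim, pixelSizeMm,
                               center = NULL, maxAttempts = 50L) {
  ratio <- cfg@gridRatio
  nHi <- imageDim * ratio
  hiPxMm <- pixelSizeMm / ratio
  hiPxAreaCm2 <- (hiPxMm / 10)^2
  if (is.null(center)) center <- c(imageDim, imageDim) / 2
  centerHi <- (center - 0.5) * ratio + 0.5
  maxAreaCm2 <- (imageDim * pixelSizeMm / 10)^2
  if (cfg@areaRangeCm2[2] > maxAreaCm2)
    stop("areaRangeCm2 exceeds the field of view")

  for (attempt in seq_len(maxAttempts)) {
    targetArea <- runif(1L, cfg@areaRangeCm2[1], cfg@areaRangeCm2[2])
    targetPx <- round(targetArea / hiPxAreaCm2)
    ## local window: lump scatter scale tied to the target tumor radius
    scatterPx <- sqrt(targetArea / pi) * 10 / hiPxMm * 0.6
    lump <- drawLumps(cfg@supportLumpy, centerHi, scatterPx, hiPxMm)
    if (!length(lump$amps)) next
    halfWin <- ceiling(3 * max(lump$widths) + 3 * scatterPx)
    r0 <- max(1L, floor(centerHi[1]) - halfWin)
    r1 <- min(nHi, ceiling(centerHi[1]) + halfWin)
    c0 <- max(1L, floor(centerHi[2]) - halfWin)
    c1 <- min(nHi, ceiling(centerHi[2]) + halfWin)
    loc <- lump$centers
    loc[, 1] <- loc[, 1] - r0 + 1; loc[, 2] <- loc[, 2] - c0 + 1
    field <- lumpySum(r1 - r0 + 1L, c1 - c0 + 1L, loc, lump$widths, lump$amps)
    if (targetPx >= length(field)) next
    thr <- sort(field, decreasing = TRUE)[targetPx]
    if (!is.finite(thr) || thr <= 0) next
    comp <- largestComponent(field >= thr)
    area <- sum(comp) * hiPxAreaCm2
    if (area >= cfg@areaRangeCm2[1] && area <= cfg@areaRangeCm2[2]) {
      support <- matrix(0, nHi, nHi)
      support[r0:r1, c0:c1] <- comp
      return(support)
    }
  }
  stop("tumor support sampling failed after ", maxAttempts,
       " attempts (configuration infeasible)")
}

#' Sample lumpy intra-tumor activity on a support
#'
#' Activity is a positive base level plus a nonnegative-clipped lumpy
#' texture, masked to the support and rescaled so that the mean activity
#' inside the support equals TBR x \code{backgroundMean} with TBR drawn
#' uniformly from \code{tbrRange}.  Strictly positive on the whole support,
#' so the support function recovered from the activity equals the input
#' support exactly.
#'
#' @param support binary high-resolution matrix (nonempty).
#' @param cfg a \code{\linkS4class{TumorConfig}}.
#' @param backgroundMean mean background activity the TBR refers to.
#' @param pixelSizeMm PET pixel size in mm.
#' @return Nonnegative matrix shaped like \code{support}.
#' @export
sampleTumorActivity <- function(support, cfg, backgroundMean, pixelSizeMm) {
  idx <- which(support == 1)
  if (!length(idx)) stop("empty tumor support")
  hiPxMm <- pixelSizeMm / cfg@gridRatio
  rc <- arrayInd(idx, dim(support))
  center <- colMeans(rc)
  scatterPx <- sqrt(length(idx) / pi)
  lump <- drawLumps(cfg@textureLumpy, center, scatterPx, hiPxMm)
  tbr <- runif(1L, cfg@tbrRange[1], cfg@tbrRange[2])
  act <- matrix(0, nrow(support), ncol(support))
  base <- 1
  if (length(lump$amps)) {
    r0 <- max(1L, min(rc[, 1])); r1 <- min(nrow(support), max(rc[, 1]))
    c0 <- max(1L, min(rc[, 2])); c1 <- min(ncol(support), max(rc[, 2]))
    loc <- lump$centers
    loc[, 1] <- loc[, 1] - r0 + 1; loc[, 2] <- loc[, 2] - c0 + 1
    tex <- lumpySum(r1 - r0 + 1L, c1 - c0 + 1L, loc, lump$widths, lump$amps)
    tex <- pmax(tex, 0)
    act[r0:r1, c0:c1] <- tex
  }
  act <- (act + base) * support
  act * (tbr * backgroundMean / mean(act[idx]))
}

#' Sample a synthetic heterogeneous background
#'
#' A stand-in for clinical background templates: an elliptical body at unit
#' base uptake with additive nonnegative lumpy heterogeneity, containing a
#' low-uptake lung ellipse (attenuated amplitude) inside which the tumor is
#' placed.  Returned at PET resolution.
#'
#' @param imageDim PET grid side (>= 16).
#' @param params \code{\linkS4class{LumpyParams}} for the heterogeneity.
#' @param pixelSizeMm PET pixel size (mm).
#' @param lungFactor multiplicative attenuation of the lung region.
#' @return A list: \code{values} (nonnegative imageDim^2 matrix),
#'   \code{lungCenter} (row, col in pixels) and \code{lungAxes}
#'   (semi-axes in pixels) locating the low-uptake region.
#' @export
sampleBackground <- function(imageDim, params, pixelSizeMm,
                             lungFactor = 0.25) {
  if (imageDim < 16L) stop("imageDim must be >= 16")
  ctr <- (imageDim + 1) / 2
  rr <- row(matrix(0, imageDim, imageDim)) - ctr
  cc <- col(matrix(0, imageDim, imageDim)) - ctr
  body <- ((rr / (0.46 * imageDim))^2 + (cc / (0.40 * imageDim))^2) <= 1
  ## lung ellipse offset to one side of the body, jittered
  lungCenter <- c(ctr + rnorm(1L, 0, 0.02 * imageDim),
                  ctr - 0.16 * imageDim + rnorm(1L, 0, 0.02 * imageDim))
  lungAxes <- c(0.20, 0.15) * imageDim * runif(2L, 0.9, 1.1)
  lung <- (((row(body) - lungCenter[1]) / lungAxes[1])^2 +
           ((col(body) - lungCenter[2]) / lungAxes[2])^2) <= 1
  n <- rpois(1L, params@meanNumLumps)
  tex <- 0
  if (n > 0L) {
    centers <- cbind(runif(n, 1, imageDim), runif(n, 1, imageDim))
    widths <- runif(n, params@lumpWidthRange[1], params@lumpWidthRange[2]) /
      pixelSizeMm
    amps <- runif(n, params@lumpAmplitudeRange[1],
                  params@lumpAmplitudeRange[2])
    tex <- pmax(lumpySum(imageDim, imageDim, centers, widths, amps), 0)
  }
  vals <- (1 + tex) * body
  vals[lung] <- vals[lung] * lungFactor
  list(values = vals, lungCenter = lungCenter, lungAxes = lungAxes)
}

#' Assemble a high-resolution phantom
#'
#' Draws a background, places a tumor inside its low-uptake lung region and
#' samples its heterogeneous activity, producing the simulated tracer
#' distribution f = f_b + f_s.
#'
#' @param cfg a \code{\linkS4class{TumorConfig}}.
#' @param backgroundParams \code{\linkS4class{LumpyParams}} for the
#'   background heterogeneity.
#' @param imageDim,pixelSizeMm PET grid geometry.
#' @return A \code{\linkS4class{HighResPhantom}}.
#' @export
samplePhantom <- function(cfg, backgroundParams, imageDim, pixelSizeMm) {
  bg <- sampleBackground(imageDim, backgroundParams, pixelSizeMm)
  jitter <- runif(2L, -0.3, 0.3) * bg$lungAxes
  center <- bg$lungCenter + jitter
  support <- sampleTumorSupport(cfg, imageDim, pixelSizeMm, center = center)
  tumorAct <- sampleTumorActivity(support, cfg,
                                  backgroundMean = mean(bg$values[bg$values > 0]),
                                  pixelSizeMm = pixelSizeMm)
  new("HighResPhantom", support = support, tumorActivity = tumorAct,
      backgroundActivity = bg$values, pixelSizeMm = pixelSizeMm,
      gridRatio = cfg@gridRatio)
}
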