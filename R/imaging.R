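## Forward model and reconstruction: image-domain Gaussian PSF, pixel-driven
## parallel-beam line integrals as a precomputed sparse matrix, Poisson
## noise, and OSEM with angle-interleaved subsets.

buildProjector <- function(imageDim, pixelSizeMm, nAngles) {
  nBins <- imageDim
  ctr <- (imageDim + 1) / 2
  ## pixel centers in mm, row index increasing = +y
  coord <- (seq_len(imageDim) - ctr) * pixelSizeMm
  x <- rep(coord, each = imageDim)   # column -> x
  y <- rep(coord, times = imageDim)  # row -> y  (column-major pixel order)
  angles <- (seq_len(nAngles) - 1L) * pi / nAngles
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  npix <- imageDim^2
  pixIdx <- seq_len(npix)
  for (k in seq_len(nAngles)) {
    t <- x * cos(angles[k]) + y * sin(angles[k])
    u <- t / pixelSizeMm + (nBins + 1) / 2   # continuous bin coordinate
    i0 <- floor(u)
    w <- u - i0
    for (part in 1:2) {
      bin <- if (part == 1L) i0 else i0 + 1
      wt <- if (part == 1L) 1 - w else w
      ok <- bin >= 1 & bin <= nBins & wt > 0
      rows <- c(rows, (k - 1L) * nBins + bin[ok])
      cols <- c(cols, pixIdx[ok])
      vals <- c(vals, wt[ok] * pixelSizeMm)
    }
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                       dims = c(nAngles * nBins, npix))
}

#' Construct a PET system model
#'
#' Precomputes the sparse parallel-beam projector so that projection and
#' back-projection are exact matrix transposes of one another.
#'
#' @param imageDim PET grid side length.
#' @param pixelSizeMm pixel (and detector bin) size in mm.
#' @param fwhmMm system resolution FWHM in mm.
#' @param nAngles projection angles over 180 degrees (default
#'   \code{imageDim}).
#' @param countScale expected total detected counts per slice.
#' @param gridRatio high-resolution grid ratio for the tumor path.
#' @return A \code{\linkS4class{SystemModel}}.
#' @examples
#' sys <- systemModel(32, pixelSizeMm = 4.07, fwhmMm = 5)
#' @export
systemModel <- function(imageDim, pixelSizeMm, fwhmMm, nAngles = imageDim,
                        countScale = 5e5, gridRatio = 8L) {
  obj <- new("SystemModel", fwhmMm = as.numeric(fwhmMm),
             imageDim = as.integer(imageDim),
             pixelSizeMm = as.numeric(pixelSizeMm),
             nAngles = as.integer(nAngles),
             countScale = as.numeric(countScale),
             gridRatio = as.integer(gridRatio),
             projector = NULL)
  obj@projector <- buildProjector(obj@imageDim, obj@pixelSizeMm, obj@nAngles)
  obj
}

sinogramFromVector <- function(v, sys, meta = list()) {
  new("Sinogram",
      values = matrix(pmax(v, 0), nrow = sys@nAngles, byrow = TRUE),
      binSizeMm = sys@pixelSizeMm, meta = meta)
}

sinogramToVector <- function(sino) as.numeric(t(sino@values))

#' Forward-project an activity grid
#'
#' Applies the Gaussian system blur (in the image domain) followed by
#' parallel-beam line integrals.  A high-resolution input is blurred at its
#' native resolution and integrated onto the PET grid before projection, so
#' tumor and background sinograms live on the same bin grid and are
#' addable.  The operation is linear.
#'
#' @param activity nonnegative matrix, either imageDim^2 (\code{highRes =
#'   FALSE}) or (imageDim * gridRatio)^2 (\code{highRes = TRUE}).
#' @param sys a \code{\linkS4class{SystemModel}}.
#' @param highRes whether \code{activity} lives on the high-resolution grid.
#' @param blur apply the system PSF (disable only for operator tests).
#' @return A \code{\linkS4class{Sinogram}}.
#' @export
forwardProject <- function(activity, sys, highRes = FALSE, blur = TRUE) {
  n <- sys@imageDim
  if (highRes) {
    if (!all(dim(activity) == n * sys@gridRatio))
      stop("high-resolution activity grid does not match the system model")
    sigmaHi <- fwhmToSigma(sys@fwhmMm) / (sys@pixelSizeMm / sys@gridRatio)
    if (blur) activity <- gaussianBlur(activity, sigmaHi)
    img <- blockReduce(activity, sys@gridRatio, "mean")
  } else {
    if (!all(dim(activity) == n))
      stop("activity grid does not match the system model")
    img <- if (blur)
      gaussianBlur(activity, fwhmToSigma(sys@fwhmMm) / sys@pixelSizeMm)
    else activity
  }
  sinogramFromVector(as.numeric(sys@projector %*% as.numeric(img)), sys)
}

#' Back-project a sinogram (adjoint of \code{forwardProject})
#'
#' @param sino a \code{\linkS4class{Sinogram}}.
#' @param sys the matching \code{\linkS4class{SystemModel}}.
#' @param blur include the (self-adjoint) PSF so the operator is the exact
#'   adjoint of the blurred forward projection.
#' @return Matrix of size imageDim^2.
#' @export
backProject <- function(sino, sys, blur = TRUE) {
  img <- matrix(as.numeric(Matrix::t(sys@projector) %*%
                             sinogramToVector(sino)),
                sys@imageDim, sys@imageDim)
  if (blur)
    img <- gaussianBlur(img, fwhmToSigma(sys@fwhmMm) / sys@pixelSizeMm)
  img
}

#' Add two sinograms on the same geometry
#'
#' Tumor and background projections are combined in the projection domain,
#' so reconstruction acts on their sum and noise texture is shared.
#'
#' @param a,b \code{\linkS4class{Sinogram}} objects with matching geometry.
#' @return A \code{\linkS4class{Sinogram}}.
#' @export
combineSinograms <- function(a, b) {
  if (!all(dim(a@values) == dim(b@values)) ||
      abs(a@binSizeMm - b@binSizeMm) > 1e-9)
    stop("sinogram geometries do not match")
  new("Sinogram", values = a@values + b@values, binSizeMm = a@binSizeMm,
      meta = c(a@meta, b@meta))
}

#' Apply Poisson noise to a sinogram
#'
#' The noiseless sinogram is scaled so its total equals
#' \code{sys@countScale} expected counts, then each bin is replaced by a
#' Poisson draw.  The scale factor is recorded in the metadata.
#'
#' @param sino noiseless \code{\linkS4class{Sinogram}}.
#' @param sys a \code{\linkS4class{SystemModel}}.
#' @return A \code{\linkS4class{Sinogram}} of integer counts.
#' @export
poissonize <- function(sino, sys) {
  if (any(sino@values < 0)) stop("negative sinogram bins")
  tot <- sum(sino@values)
  if (tot <= 0) stop("empty sinogram")
  scale <- sys@countScale / tot
  lam <- sino@values * scale
  counts <- matrix(rpois(length(lam), lam), nrow(lam), ncol(lam))
  new("Sinogram", values = counts, binSizeMm = sino@binSizeMm,
      meta = c(sino@meta, list(countScaleFactor = scale)))
}

## Angle-interleaved subsets, sized as evenly as possible.
osemSubsets <- function(nAngles, nSubsets) {
  lapply(seq_len(nSubsets), function(k) seq(k, nAngles, by = nSubsets))
}

## Poisson log-likelihood of counts y under expectation lambda (bins with
## lambda = 0 and y = 0 contribute 0).
poissonLogLik <- function(y, lambda) {
  eps <- 1e-12
  sum(y * log(pmax(lambda, eps)) - lambda)
}

#' Ordered-subsets expectation maximization reconstruction
#'
#' Standard multiplicative OSEM updates cycling angle-interleaved subsets.
#' With \code{nSubsets = 1} this is MLEM.  The reconstruction operator uses
#' the geometric projector only (no resolution modeling), so the
#' reconstructed image retains the system blur.
#'
#' @param sino measured (or noiseless) \code{\linkS4class{Sinogram}}.
#' @param sys a \code{\linkS4class{SystemModel}}.
#' @param nSubsets number of subsets (default 21).
#' @param nIterations full iterations, each cycling all subsets (default 2).
#' @param init positive initial image matrix, or \code{"uniform"}.
#' @return A \code{\linkS4class{ReconImage}}; nonnegative by construction.
#' @export
osem <- function(sino, sys, nSubsets = 21L, nIterations = 2L,
                 init = "uniform") {
  n <- sys@imageDim
  if (identical(init, "uniform")) init <- matrix(1, n, n)
  if (any(init <= 0)) stop("init must be strictly positive")
  subsets <- osemSubsets(sys@nAngles, as.integer(nSubsets))
  nBins <- n
  y <- sinogramToVector(sino)
  A <- sys@projector
  parts <- lapply(subsets, function(s) {
    rowsIdx <- as.integer(outer(seq_len(nBins), (s - 1L) * nBins, `+`))
    As <- A[rowsIdx, , drop = FALSE]
    list(At = Matrix::t(As), As = As, y = y[rowsIdx],
         sens = as.numeric(Matrix::colSums(As)))
  })
  f <- as.numeric(init)
  eps <- 1e-12
  for (it in seq_len(nIterations)) {
    for (p in parts) {
      proj <- as.numeric(p$As %*% f)
      ratio <- ifelse(proj > eps, p$y / proj, 0)
      back <- as.numeric(p$At %*% ratio)
      f <- ifelse(p$sens > eps, f * back / p$sens, 0)
    }
  }
  reconImage(matrix(pmax(f, 0), n, n), sys@pixelSizeMm,
             meta = list(nSubsets = as.integer(nSubsets),
                         nIterations = as.integer(nIterations)))
}

#' Simulate one reconstructed PET slice from a phantom
#'
#' Projects tumor (high-resolution path) and background (PET-resolution
#' path) separately, adds the sinograms, applies Poisson noise, and
#' reconstructs with OSEM.
#'
#' @param phantom a \code{\linkS4class{HighResPhantom}}.
#' @param sys a \code{\linkS4class{SystemModel}}.
#' @param nSubsets,nIterations OSEM settings.
#' @param noise apply Poisson noise (default TRUE).
#' @return A \code{\linkS4class{ReconImage}}.
#' @export
simulateSlice <- function(phantom, sys, nSubsets = 21L, nIterations = 2L,
                          noise = TRUE) {
  sTum <- forwardProject(phantom@tumorActivity, sys, highRes = TRUE)
  sBg <- forwardProject(phantom@backgroundActivity, sys, highRes = FALSE)
  sino <- combineSinograms(sTum, sBg)
  if (noise) sino <- poissonize(sino, sys)
  osem(sino, sys, nSubsets = nSubsets, nIterations = nIterations)
}
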