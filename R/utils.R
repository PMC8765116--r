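## Internal numeric helpers shared across modules.

## 1D Gaussian convolution matrix with zero padding, truncated at 4 sigma.
## The kernel integrates the Gaussian over each pixel bin (not point
## samples), so the discrete PSF carries the nominal FWHM even when sigma
## is below one pixel.  Symmetric, so the 2D separable blur
## K %*% X %*% t(K) is self-adjoint.
gaussKernelMatrix <- function(n, sigmaPx) {
  if (sigmaPx <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigmaPx))
  edges <- seq(-half - 0.5, half + 0.5)
  k <- diff(stats::pnorm(edges, sd = sigmaPx))
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (off in seq(-half, half)) {
    idx <- seq_len(n) + off
    ok <- idx >= 1L & idx <= n
    K[cbind(which(ok), idx[ok])] <- K[cbind(which(ok), idx[ok])] +
      k[off + half + 1L]
  }
  K
}

## Isotropic Gaussian blur (zero boundary). sigma in pixels of `x`.
gaussianBlur <- function(x, sigmaPx) {
  if (sigmaPx <= 0) return(x)
  K <- gaussKernelMatrix(nrow(x), sigmaPx)
  if (ncol(x) == nrow(x)) K2 <- K else K2 <- gaussKernelMatrix(ncol(x), sigmaPx)
  K %*% x %*% t(K2)
}

fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

## Sum (or mean) over ratio x ratio blocks; dims must divide exactly.
blockReduce <- function(x, ratio, op = c("sum", "mean")) {
  op <- match.arg(op)
  n1 <- nrow(x); n2 <- ncol(x)
  if (n1 %% ratio != 0L || n2 %% ratio != 0L)
    stop("grid dimensions are not divisible by the grid ratio")
  m1 <- n1 %/% ratio; m2 <- n2 %/% ratio
  dim(x) <- c(ratio, m1, ratio, m2)
  out <- colSums(aperm(x, c(1, 3, 2, 4)), dims = 2)
  if (op == "mean") out <- out / ratio^2
  out
}

## Nearest-neighbor upsampling by an integer factor.
blockExpand <- function(x, ratio) {
  x[rep(seq_len(nrow(x)), each = ratio), rep(seq_len(ncol(x)), each = ratio)]
}

## Sum of N ~ Pois(meanNumLumps) isotropic Gaussian lumps evaluated on the
## pixel grid rows x cols (pixel units).  centers: 2-column matrix in pixel
## coordinates; widths (sd) in pixels; amplitudes free.  Each lump is
## separable, so it is accumulated as an outer product.
lumpySum <- function(nrows, ncols, centers, widthsPx, amplitudes) {
  field <- matrix(0, nrows, ncols)
  if (!length(amplitudes)) return(field)
  rr <- seq_len(nrows); cc <- seq_len(ncols)
  for (i in seq_along(amplitudes)) {
    gr <- exp(-(rr - centers[i, 1])^2 / (2 * widthsPx[i]^2))
    gc <- exp(-(cc - centers[i, 2])^2 / (2 * widthsPx[i]^2))
    field <- field + amplitudes[i] * (gr %o% gc)
  }
  field
}

## Largest connected component (8-connectivity) of a binary matrix.
largestComponent <- function(mask) {
  if (!any(mask > 0)) return(mask * 0)
  lab <- EBImage::bwlabel(mask > 0)
  tab <- tabulate(lab[lab > 0])
  (lab == which.max(tab)) * 1
}

## Shoelace polygon area (absolute).
polygonArea <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  abs(sum(x * y[c(2:n, 1)] - y * x[c(2:n, 1)])) / 2
}

## Separable boxcar moving average with reflected boundaries.
boxcar <- function(x, width) {
  if (width == 1L) return(x)
  half <- (width - 1L) %/% 2L
  reflectPad <- function(v, h) c(v[h:1], v, v[length(v):(length(v) - h + 1L)])
  smooth1 <- function(v) {
    p <- reflectPad(v, half)
    cs <- c(0, cumsum(p))
    (cs[(width + 1L):length(cs)] - cs[1:(length(cs) - width)]) / width
  }
  x <- apply(x, 2L, smooth1)
  t(apply(x, 1L, smooth1))
}

## Student-t mean and 95% CI.
meanCi95 <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least two values")
  m <- mean(x)
  half <- qt(0.975, n - 1L) * stats::sd(x) / sqrt(n)
  c(mean = m, ci_low = m - half, ci_high = m + half)
}
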