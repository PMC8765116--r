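# Shared small-scale fixtures, built in code at load time.

# Desk-scale system: 32x32 grid, clinical pixel/FWHM ratio, grid ratio 4.
smallSystem <- function(nAngles = 42L, fwhmMm = 5, countScale = 2e5) {
  systemModel(32, pixelSizeMm = 4.07, fwhmMm = fwhmMm, nAngles = nAngles,
              countScale = countScale, gridRatio = 4L)
}

smallTumorConfig <- function() tumorConfig(gridRatio = 4L)

smallBackgroundParams <- function() lumpyParams(6, c(15, 40), c(0.2, 0.6))

# A filled disk support on an n x n grid.
diskMatrix <- function(n, radius, center = (n + 1) / 2) {
  m <- matrix(0, n, n)
  m[(row(m) - center)^2 + (col(m) - center)^2 <= radius^2] <- 1
  m
}

# Random binary high-res support (iid pixels), for exactness oracles.
randomSupport <- function(n, p = 0.4) {
  matrix(as.numeric(runif(n * n) < p), n, n)
}

# Second-moment FWHM (mm) of a nonnegative image.
momentFwhmMm <- function(img, pixelSizeMm) {
  w <- img / sum(img)
  muR <- sum(row(img) * w); muC <- sum(col(img) * w)
  v <- (sum((row(img) - muR)^2 * w) + sum((col(img) - muC)^2 * w)) / 2
  2 * sqrt(2 * log(2)) * sqrt(v) * pixelSizeMm
}
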