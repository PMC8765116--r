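## Ground-truth tumor-fraction areas: exact sub-pixel counting of a
## high-resolution binary support (simulated s(r), or a manual tumor mask
## drawn at a finer, nested, aligned grid) over each PET pixel.

#' Compute the ground-truth TFA map from a high-resolution support
#'
#' The TFA of PET pixel m is the number of set high-resolution pixels that
#' fall inside it divided by \code{gridRatio^2}: the pixel-counting
#' discretization of the area integral of the support against the pixel
#' indicator function.  Computed from integer counts, so it is exact.
#'
#' @param support binary matrix whose dimensions are an integer multiple
#'   (\code{gridRatio}) of the PET grid, or a
#'   \code{\linkS4class{HighResPhantom}}.
#' @param gridRatio high-res pixels per PET pixel per axis (ignored when
#'   \code{support} is a phantom).
#' @param pixelAreaCm2 PET pixel area in cm^2 (ignored for a phantom, where
#'   it is derived from the pixel size).
#' @return A \code{\linkS4class{TFAMap}}.
#' @examples
#' s <- matrix(0, 16, 16); s[5:12, 5:12] <- 1
#' computeTFA(s, gridRatio = 4, pixelAreaCm2 = 0.1656)
#' @export
computeTFA <- function(support, gridRatio, pixelAreaCm2) {
  if (is(support, "HighResPhantom")) {
    gridRatio <- support@gridRatio
    pixelAreaCm2 <- (support@pixelSizeMm / 10)^2
    support <- support@support
  }
  gridRatio <- as.integer(gridRatio)
  if (any(dim(support) %% gridRatio != 0L))
    stop("support dimensions are not divisible by gridRatio")
  if (!all(support %in% c(0, 1))) stop("support must be binary")
  counts <- blockReduce(support, gridRatio, "sum")
  tfaMap(counts / gridRatio^2, pixelAreaCm2)
}

#' Tumor area of a TFA map
#'
#' The L1 norm of the map times the pixel area: the (estimated or true)
#' tumor cross-section area in cm^2.
#'
#' @param map a \code{\linkS4class{TFAMap}}.
#' @return Area in cm^2.
#' @export
tumorArea <- function(map) {
  stopifnot(is(map, "TFAMap"))
  map@pixelAreaCm2 * sum(map@values)
}

#' Binarize a TFA map
#'
#' @param map a \code{\linkS4class{TFAMap}}.
#' @param level threshold in (0, 1); pixels with TFA >= level are set.
#' @return Binary matrix.
#' @export
binarizeTFA <- function(map, level = 0.5) {
  stopifnot(is(map, "TFAMap"))
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  (map@values >= level) * 1
}
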