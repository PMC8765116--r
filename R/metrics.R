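## Evaluation metrics: ensemble MSE on the estimation task, fuzzy confusion
## cardinalities and Dice/Jaccard on the segmentation task, Student-t CIs,
## paired t-tests, and isocontour topographic maps.

asValueList <- function(maps) {
  lapply(maps, function(m) if (is(m, "TFAMap")) m@values else m)
}

checkPaired <- function(truths, estimates) {
  if (!length(truths) || length(truths) != length(estimates))
    stop("truths and estimates must be nonempty paired lists")
  t0 <- asValueList(truths); e0 <- asValueList(estimates)
  for (i in seq_along(t0))
    if (!all(dim(t0[[i]]) == dim(e0[[i]])))
      stop("shape mismatch in pair ", i)
  list(t = t0, e = e0)
}

#' Pixel-wise ensemble mean squared error
#'
#' Empirical mean, over (tumor, noise-realization) pairs, of the squared L2
#' distance between estimated and true TFA maps.
#'
#' @param truths,estimates paired lists of \code{\linkS4class{TFAMap}}s (or
#'   plain matrices).
#' @return Nonnegative scalar.
#' @export
pixelwiseEMSE <- function(truths, estimates) {
  p <- checkPaired(truths, estimates)
  mean(vapply(seq_along(p$t),
              function(i) sum((p$e[[i]] - p$t[[i]])^2), numeric(1)))
}

#' Normalized area ensemble mean squared error
#'
#' Mean over pairs of |Ahat - A|^2 / A^2, where areas are the L1 norms of
#' the maps times the pixel area (which cancels in the ratio).
#'
#' @param truths,estimates paired lists of \code{\linkS4class{TFAMap}}s.
#' @return Nonnegative scalar.
#' @export
normalizedAreaEMSE <- function(truths, estimates) {
  p <- checkPaired(truths, estimates)
  a <- vapply(p$t, sum, numeric(1))
  ahat <- vapply(p$e, sum, numeric(1))
  if (any(a <= 0)) stop("every true area must be positive")
  mean((ahat - a)^2 / a^2)
}

#' Ensemble-average bias map
#'
#' Per-pixel signed mean of (estimate - truth) over P tumors x N noise
#' realizations.  Elements near zero indicate the estimator is unbiased in
#' the Bayesian sense.
#'
#' @param truths,estimates paired lists covering all P x N combinations.
#' @param P,N numbers of tumors and noise realizations
#'   (\code{P * N == length(truths)}).
#' @return Matrix of per-pixel bias.
#' @export
ensembleBias <- function(truths, estimates, P = length(truths), N = 1L) {
  p <- checkPaired(truths, estimates)
  if (P * N != length(p$t)) stop("P * N must equal the number of pairs")
  acc <- 0
  for (i in seq_along(p$t)) acc <- acc + (p$e[[i]] - p$t[[i]])
  acc / (P * N)
}

#' Fuzzy confusion cardinalities for continuous membership maps
#'
#' TP = sum min(ahat, a); FP = sum max(ahat - a, 0);
#' TN = sum min(1 - ahat, 1 - a); FN = sum max(a - ahat, 0).
#' On binary maps these reduce to the classical counts, and
#' TP + FP + TN + FN = M identically.
#'
#' @param truth,estimate \code{\linkS4class{TFAMap}}s or matrices with
#'   values in [0, 1], same shape.
#' @return A \code{\linkS4class{FuzzyConfusion}}.
#' @export
fuzzyConfusion <- function(truth, estimate) {
  a <- if (is(truth, "TFAMap")) truth@values else truth
  ah <- if (is(estimate, "TFAMap")) estimate@values else estimate
  if (!all(dim(a) == dim(ah))) stop("shape mismatch")
  if (any(a < 0 | a > 1 | ah < 0 | ah > 1)) stop("values must lie in [0, 1]")
  new("FuzzyConfusion",
      tp = sum(pmin(ah, a)), fp = sum(pmax(ah - a, 0)),
      tn = sum(pmin(1 - ah, 1 - a)), fn = sum(pmax(a - ah, 0)),
      nPixels = length(a))
}

#' Dice and Jaccard similarity coefficients from fuzzy cardinalities
#'
#' DSC = 2TP / (2TP + FP + FN), JSC = TP / (TP + FP + FN); when both maps
#' are identically zero (empty denominator) both are defined as 1.
#'
#' @param confusion a \code{\linkS4class{FuzzyConfusion}}.
#' @return Named numeric vector \code{c(dsc = , jsc = )}, both in [0, 1].
#' @export
dscJsc <- function(confusion) {
  stopifnot(is(confusion, "FuzzyConfusion"))
  denom <- confusion@tp + confusion@fp + confusion@fn
  if (denom <= 0) return(c(dsc = 1, jsc = 1))
  c(dsc = 2 * confusion@tp / (confusion@tp + denom),
    jsc = confusion@tp / denom)
}

#' Mean with Student-t 95% confidence interval
#'
#' @param x numeric vector, length >= 2.
#' @return Named vector (mean, ci_low, ci_high).
#' @export
summarizeMetric <- function(x) meanCi95(x)

#' Two-sided paired t-test p-value
#'
#' Degenerate inputs (zero-variance differences) are resolved to p = 1 when
#' all differences are zero, and p = 0 otherwise.
#'
#' @param x,y paired numeric vectors, length >= 2.
#' @return p-value.
#' @export
pairedTest <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must be paired with length >= 2")
  d <- x - y
  if (stats::sd(d) == 0) return(if (all(d == 0)) 1 else 0)
  t.test(x, y, paired = TRUE)$p.value
}

#' Isocontours of a TFA map
#'
#' Level sets on the pixel-centered grid (marching squares, via
#' \code{grDevices::contourLines}).  The boundary levels 0 and 1 are
#' evaluated at 0 + eps and 1 - eps so they bound the tumor support and the
#' fully-tumor region respectively.
#'
#' @param map a \code{\linkS4class{TFAMap}} or matrix.
#' @param levels TFA levels, each in [0, 1] (default 0, 1/3, 2/3, 1).
#' @param eps offset applied to the boundary levels 0 and 1.
#' @return Named list (one element per level) of lists of contour polylines
#'   with components \code{x}, \code{y} in pixel coordinates.
#' @export
isocontours <- function(map, levels = c(0, 1/3, 2/3, 1), eps = 1e-6) {
  v <- if (is(map, "TFAMap")) map@values else map
  if (any(levels < 0 | levels > 1)) stop("levels must lie in [0, 1]")
  adj <- pmin(pmax(levels, eps), 1 - eps)
  if (max(v) == min(v)) {   # constant map: no level crossings anywhere
    out <- rep(list(list()), length(adj))
    names(out) <- format(levels, digits = 4)
    return(out)
  }
  out <- lapply(adj, function(l) {
    cl <- grDevices::contourLines(x = seq_len(nrow(v)), y = seq_len(ncol(v)),
                                  z = v, levels = l)
    lapply(cl, function(p) list(x = p$x, y = p$y))
  })
  names(out) <- format(levels, digits = 4)
  out
}

## Total enclosed area of an isocontour level (sum of shoelace areas of its
## closed polylines), used for nesting checks.
isocontourArea <- function(contours) {
  sum(vapply(contours, function(p) polygonArea(p$x, p$y), numeric(1)))
}
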