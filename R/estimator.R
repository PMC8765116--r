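## The TFA estimator: an encoder-decoder network trained with the aggregate
## binary cross-entropy cost.  Because the cost's population minimizer is
## the posterior mean of the TFA given the image, the trained network is a
## posterior-mean estimator; a numerical-quadrature oracle on a scalar toy
## observation model is provided to verify this property empirically.

#' Aggregate binary cross-entropy cost between TFA maps
#'
#' Sum over pixels of \code{-a log(ahat) - (1 - a) log(1 - ahat)}, with the
#' log arguments floored at \code{clampEps}.  Minimized (over
#' \code{estimate}) at \code{estimate == truth}, where it equals the sum of
#' per-pixel binary entropies.
#'
#' @param truth,estimate \code{\linkS4class{TFAMap}}s or matrices of equal
#'   shape with values in [0, 1].
#' @param clampEps floor for the log arguments.
#' @return Nonnegative scalar.
#' @export
bceCost <- function(truth, estimate, clampEps = 1e-7) {
  a <- if (is(truth, "TFAMap")) truth@values else truth
  ah <- if (is(estimate, "TFAMap")) estimate@values else estimate
  if (!all(dim(a) == dim(ah))) stop("shape mismatch")
  ah <- pmin(pmax(ah, clampEps), 1 - clampEps)
  -sum(a * log(ah) + (1 - a) * log(1 - ah))
}

## He-normal initial weights for the layer table of a NetworkConfig,
## drawn from the current R RNG stream.
initWeights <- function(cfg) {
  dims <- .unetLayerDims(cfg@depth, cfg@baseChannels)
  w <- vector("list", 2L * nrow(dims))
  for (i in seq_len(nrow(dims))) {
    fanIn <- dims[i, "cin"] * dims[i, "kernel"]^2
    w[[2L * i - 1L]] <- matrix(rnorm(dims[i, "cout"] * fanIn,
                                     sd = sqrt(2 / fanIn)),
                               dims[i, "cout"], fanIn)
    w[[2L * i]] <- numeric(dims[i, "cout"])
  }
  w
}

#' Build an untrained TFA estimator
#'
#' Initializes the encoder-decoder (He-normal kernels, zero biases) from
#' the current RNG state.  Every output of the untrained network already
#' lies strictly in (0, 1) because of the logistic output squash.
#'
#' @param cfg a \code{\linkS4class{NetworkConfig}}.
#' @return A \code{\linkS4class{TrainedEstimator}} with empty history.
#' @export
buildEstimator <- function(cfg) {
  stopifnot(is(cfg, "NetworkConfig"))
  new("TrainedEstimator", weights = initWeights(cfg), config = cfg,
      history = numeric(0), meta = list(normalization = "max"))
}

## Stack images (matrices or ReconImage/TFAMap) into an npix x n matrix.
stackMaps <- function(maps, inputDim) {
  vapply(maps, function(m) {
    v <- if (is(m, "ReconImage") || is(m, "TFAMap")) values(m) else m
    if (!all(dim(v) == inputDim)) stop("map dimensions do not match inputDim")
    as.numeric(v)
  }, numeric(inputDim^2))
}

normalizeImage <- function(v) {
  mx <- max(v)
  if (mx <= 0) v else v / mx
}

#' Train the TFA estimator
#'
#' Minimizes the aggregate BCE cost (per-image pixel sum, minibatch mean)
#' with Adam.  Input images are individually normalized to unit maximum
#' before entering the network.  Initialization and minibatch shuffling are
#' driven by \code{trainCfg@seed}, so training is deterministic.
#'
#' @param images list of \code{\linkS4class{ReconImage}}s (or matrices).
#' @param tfaMaps paired list of ground-truth \code{\linkS4class{TFAMap}}s
#'   (or matrices); for the classification baseline these may be binary.
#' @param netCfg a \code{\linkS4class{NetworkConfig}}.
#' @param trainCfg a \code{\linkS4class{TrainingConfig}}.
#' @param normalize input normalization rule: \code{"max"} (divide each
#'   image by its maximum; appropriate for PET images whose absolute scale
#'   is arbitrary) or \code{"none"} (raw values, as in the toy model where
#'   the observation scale is meaningful).
#' @param warmStart optional \code{\linkS4class{TrainedEstimator}} whose
#'   weights seed the optimization (e.g. to continue training at a lower
#'   learning rate); its architecture must match \code{netCfg}.
#' @return A \code{\linkS4class{TrainedEstimator}} with per-epoch mean
#'   training cost in \code{@history} (appended to the warm start's).
#' @export
trainEstimator <- function(images, tfaMaps, netCfg, trainCfg,
                           normalize = c("max", "none"), warmStart = NULL) {
  normalize <- match.arg(normalize)
  if (length(images) < 2L || length(images) != length(tfaMaps))
    stop("need >= 2 paired (image, TFA map) training samples")
  X <- stackMaps(images, netCfg@inputDim)
  if (normalize == "max") X <- apply(X, 2L, normalizeImage)
  Y <- stackMaps(tfaMaps, netCfg@inputDim)
  if (any(Y < 0 | Y > 1)) stop("target values must lie in [0, 1]")
  n <- ncol(X)
  set.seed(trainCfg@seed)
  w <- if (is.null(warmStart)) initWeights(netCfg) else warmStart@weights
  order <- vapply(seq_len(trainCfg@epochs), function(e) sample.int(n),
                  integer(n))
  fit <- .unetTrain(w, X, Y, netCfg@inputDim, netCfg@depth,
                    netCfg@baseChannels, order, trainCfg@batchSize,
                    trainCfg@learningRate, trainCfg@clampEps)
  hist0 <- if (is.null(warmStart)) numeric(0) else warmStart@history
  new("TrainedEstimator", weights = fit$weights, config = netCfg,
      history = c(hist0, as.numeric(fit$history)),
      meta = list(seed = trainCfg@seed, normalization = normalize,
                  trainCfg = trainCfg))
}

#' Predict a TFA map from a PET image
#'
#' @param estimator a \code{\linkS4class{TrainedEstimator}}.
#' @param image a \code{\linkS4class{ReconImage}} or matrix matching the
#'   training dimensions.
#' @param pixelAreaCm2 pixel area for the returned map; derived from the
#'   image when it is a \code{ReconImage}.
#' @return A \code{\linkS4class{TFAMap}} with all values in (0, 1).
#' @export
predictTFA <- function(estimator, image, pixelAreaCm2 = NULL) {
  stopifnot(is(estimator, "TrainedEstimator"))
  if (is.null(pixelAreaCm2))
    pixelAreaCm2 <- if (is(image, "ReconImage"))
      (image@pixelSizeMm / 10)^2 else 1
  cfg <- estimator@config
  x <- stackMaps(list(image), cfg@inputDim)
  if (!identical(estimator@meta$normalization, "none"))
    x <- apply(x, 2L, normalizeImage)
  out <- .unetForward(estimator@weights, x, cfg@inputDim, cfg@depth,
                      cfg@baseChannels)
  tfaMap(matrix(out[, 1L], cfg@inputDim, cfg@inputDim), pixelAreaCm2)
}

## Batch prediction (shared normalization rule), returns list of TFAMaps.
predictTFABatch <- function(estimator, images, pixelAreaCm2) {
  cfg <- estimator@config
  X <- stackMaps(images, cfg@inputDim)
  if (!identical(estimator@meta$normalization, "none"))
    X <- apply(X, 2L, normalizeImage)
  out <- .unetForward(estimator@weights, X, cfg@inputDim, cfg@depth,
                      cfg@baseChannels)
  lapply(seq_len(ncol(out)), function(i)
    tfaMap(matrix(out[, i], cfg@inputDim, cfg@inputDim), pixelAreaCm2))
}

#' Cross-validate estimator hyperparameters
#'
#' k-fold cross-validation over a declared grid of (learning rate, depth,
#' base channels) combinations; the selection criterion is the validation
#' BCE cost.
#'
#' @param images,tfaMaps paired training lists.
#' @param grid data.frame with columns \code{learningRate}, \code{depth},
#'   \code{baseChannels}.
#' @param inputDim image side length.
#' @param trainCfg a \code{\linkS4class{TrainingConfig}} (supplies epochs,
#'   batch size, folds, seed).
#' @return The grid with an added \code{meanValCost} column and an
#'   attribute \code{"folds"} holding the per-fold costs.
#' @export
crossValidate <- function(images, tfaMaps, grid, inputDim, trainCfg) {
  n <- length(images)
  k <- trainCfg@nFolds
  if (n < k) stop("fewer samples than folds")
  set.seed(trainCfg@seed)
  foldId <- sample(rep(seq_len(k), length.out = n))
  perFold <- matrix(NA_real_, nrow(grid), k)
  for (gi in seq_len(nrow(grid))) {
    netCfg <- networkConfig(inputDim, depth = grid$depth[gi],
                            baseChannels = grid$baseChannels[gi])
    tc <- trainingConfig(learningRate = grid$learningRate[gi],
                         batchSize = trainCfg@batchSize,
                         epochs = trainCfg@epochs, nFolds = k,
                         seed = trainCfg@seed, clampEps = trainCfg@clampEps)
    for (f in seq_len(k)) {
      tr <- which(foldId != f); va <- which(foldId == f)
      est <- trainEstimator(images[tr], tfaMaps[tr], netCfg, tc)
      preds <- predictTFABatch(est, images[va], 1)
      perFold[gi, f] <- mean(vapply(seq_along(va), function(i)
        bceCost(tfaMaps[[va[i]]], preds[[i]], tc@clampEps), numeric(1)))
    }
  }
  grid$meanValCost <- rowMeans(perFold)
  attr(grid, "folds") <- perFold
  grid
}

## ---------------------------------------------------------------------------
## Scalar toy model: numerical posterior-mean oracle
## ---------------------------------------------------------------------------

toyPriorDensity <- function(model, v) {
  switch(model@prior,
         uniform = rep(1, length(v)),
         beta = stats::dbeta(v, model@priorParams[1], model@priorParams[2]),
         stop("two_point prior has no density; handled separately"))
}

#' Numerical posterior-mean oracle for the scalar toy model
#'
#' For the observation model (observation = v + Gaussian noise, v in [0,1]
#' from the prior), computes E[v | observation] by quadrature (trapezoid on
#' \code{quadratureN} nodes; exact summation for a two-point prior).  The
#' BCE-trained estimator must converge to this function.
#'
#' @param model a \code{\linkS4class{ToyPosteriorModel}}.
#' @param observation numeric vector of observed values.
#' @return Posterior means in [0, 1], one per observation.
#' @export
posteriorMeanOracle <- function(model, observation) {
  stopifnot(is(model, "ToyPosteriorModel"))
  s <- model@noiseSigma
  if (model@prior == "two_point") {
    pp <- model@priorParams
    if (length(pp) != 3L || pp[3] <= 0 || pp[3] >= 1)
      stop("two_point prior needs (v1, v2, prob1) with prob1 in (0,1)")
    w1 <- pp[3] * dnorm(observation - pp[1], sd = s)
    w2 <- (1 - pp[3]) * dnorm(observation - pp[2], sd = s)
    if (any(w1 + w2 <= 0)) stop("degenerate posterior")
    return((w1 * pp[1] + w2 * pp[2]) / (w1 + w2))
  }
  v <- seq(0, 1, length.out = model@quadratureN)
  dens <- toyPriorDensity(model, v)
  if (all(dens == 0)) stop("degenerate prior")
  vapply(observation, function(f) {
    w <- dens * dnorm(f - v, sd = s)
    ## trapezoid weights
    tw <- c(0.5, rep(1, length(v) - 2L), 0.5)
    den <- sum(tw * w)
    if (den <= 0) stop("degenerate posterior at observation ", f)
    sum(tw * w * v) / den
  }, numeric(1))
}

#' Sample images from the scalar toy model
#'
#' Each pixel is an i.i.d. draw v from the prior, observed as v + Gaussian
#' noise; the TFA target map is v itself.  Used to verify the
#' posterior-mean property of BCE training on a model whose posterior is
#' numerically tractable.
#'
#' @param model a \code{\linkS4class{ToyPosteriorModel}}.
#' @param n number of images.
#' @param dim image side length.
#' @return List with paired lists \code{images} (observations, matrices)
#'   and \code{truths} (matrices of v).
#' @export
sampleToyData <- function(model, n, dim) {
  truths <- vector("list", n); images <- vector("list", n)
  for (i in seq_len(n)) {
    v <- switch(model@prior,
                uniform = runif(dim^2),
                beta = stats::rbeta(dim^2, model@priorParams[1],
                                    model@priorParams[2]),
                two_point = ifelse(runif(dim^2) < model@priorParams[3],
                                   model@priorParams[1],
                                   model@priorParams[2]))
    truths[[i]] <- matrix(v, dim, dim)
    images[[i]] <- matrix(v + rnorm(dim^2, sd = model@noiseSigma), dim, dim)
  }
  list(images = images, truths = truths)
}
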