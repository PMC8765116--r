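test_that("the BCE cost matches its analytic values and stationarity", {
  one <- matrix(1, 1, 1)
  expect_equal(bceCost(one, one), 0, tolerance = 1e-6)
  half <- matrix(0.5, 1, 1)
  expect_equal(bceCost(half, half), log(2))
  # minimum over the estimate sits at the truth, value = binary entropy
  a <- matrix(c(0.3, 0.8), 1, 2)
  ent <- -sum(a * log(a) + (1 - a) * log(1 - a))
  expect_equal(bceCost(a, a), ent)
  expect_gt(bceCost(a, a + 0.05), ent)
  expect_gt(bceCost(a, a - 0.05), ent)
  # finite-difference gradient at the truth is zero
  h <- 1e-6
  g <- (bceCost(a, a + h) - bceCost(a, a - h)) / (2 * h)
  expect_lt(abs(g), 1e-4)
  expect_error(bceCost(matrix(0, 1, 2), matrix(0, 2, 1)), "mismatch")
})

test_that("network configuration validity is enforced", {
  expect_error(networkConfig(30, depth = 2), "divisible")
  expect_error(networkConfig(32, depth = 1), "depth")
  expect_error(trainingConfig(clampEps = 0.7), "clampEps")
  expect_error(trainingConfig(nFolds = 1), "nFolds")
})

test_that("untrained networks map any input into (0,1) at matching shape", {
  for (dimN in c(16L, 32L)) {
    cfg <- networkConfig(dimN, depth = 2, baseChannels = 4)
    set.seed(41)
    est <- buildEstimator(cfg)
    x <- matrix(rnorm(dimN^2), dimN, dimN)
    out <- values(predictTFA(est, x))
    expect_identical(dim(out), c(dimN, dimN))
    expect_true(all(out > 0 & out < 1))
  }
})

test_that("initialization and prediction are deterministic under a seed", {
  cfg <- networkConfig(16, depth = 2, baseChannels = 4)
  e1 <- withr::with_seed(7, buildEstimator(cfg))
  e2 <- withr::with_seed(7, buildEstimator(cfg))
  expect_identical(e1@weights, e2@weights)
  x <- matrix(runif(256), 16, 16)
  expect_identical(values(predictTFA(e1, x)), values(predictTFA(e2, x)))
})

test_that("analytic backpropagation matches finite differences", {
  cfg <- networkConfig(8, depth = 2, baseChannels = 2)
  set.seed(42)
  w <- tfaseg:::initWeights(cfg)
  X <- matrix(runif(64 * 3), 64, 3)
  Y <- matrix(runif(64 * 3), 64, 3)
  lg <- tfaseg:::.unetLossGrad(w, X, Y, 8L, 2L, 2L, 1e-7)
  set.seed(43)
  for (trial in 1:25) {
    li <- sample(length(w), 1)
    idx <- sample(length(w[[li]]), 1)
    h <- 1e-5
    wp <- w; wp[[li]][idx] <- wp[[li]][idx] + h
    wm <- w; wm[[li]][idx] <- wm[[li]][idx] - h
    fd <- (tfaseg:::.unetLossGrad(wp, X, Y, 8L, 2L, 2L, 1e-7)$loss -
           tfaseg:::.unetLossGrad(wm, X, Y, 8L, 2L, 2L, 1e-7)$loss) / (2 * h)
    an <- lg$grad[[li]][idx]
    expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-8), 1e-5)
  }
})

test_that("training reduces the cost and learns a deterministic mapping", {
  # noiseless task: the image is the TFA map scaled by 0.7, so the
  # posterior mean equals image / 0.7 and is exactly learnable
  set.seed(44)
  truths <- lapply(1:200, function(i) {
    m <- matrix(0, 16, 16)
    r <- sample(3:6, 1)
    m[(row(m) - 8.5)^2 + (col(m) - 8.5)^2 <= r^2] <- runif(1, 0.3, 1)
    m
  })
  images <- lapply(truths, function(m) 0.7 * m)
  cfg <- networkConfig(16, depth = 2, baseChannels = 6)
  tc <- trainingConfig(learningRate = 2e-3, epochs = 30, batchSize = 20,
                       seed = 5)
  est <- trainEstimator(images[1:160], truths[1:160], cfg, tc,
                        normalize = "none")
  expect_lt(tail(est@history, 1), est@history[1])
  held <- 161:200
  mae <- mean(vapply(held, function(i)
    mean(abs(values(predictTFA(est, images[[i]])) - truths[[i]])),
    numeric(1)))
  expect_lt(mae, 0.05)
  # identical seed and data give identical parameters
  est2 <- trainEstimator(images[1:160], truths[1:160], cfg, tc,
                         normalize = "none")
  expect_identical(est@weights, est2@weights)
  expect_error(trainEstimator(images[1], truths[1], cfg, tc), ">= 2")
})

test_that("the posterior-mean oracle matches analytic and Monte-Carlo answers", {
  # a point-mass prior pins the posterior
  pm <- toyPosteriorModel("two_point", c(0.7, 0.7, 0.5), noiseSigma = 0.2)
  expect_equal(posteriorMeanOracle(pm, c(-1, 0.2, 2)), rep(0.7, 3))
  # symmetric two-point prior at the midpoint
  tp <- toyPosteriorModel("two_point", c(0, 1, 0.5), noiseSigma = 0.3)
  expect_equal(posteriorMeanOracle(tp, 0.5), 0.5)
  # uniform prior vs self-normalized importance-sampling Monte Carlo
  un <- toyPosteriorModel("uniform", noiseSigma = 0.1)
  set.seed(46)
  for (obs in c(0.15, 0.5, 0.93)) {
    v <- runif(1e6)
    w <- dnorm(obs - v, sd = 0.1)
    mc <- sum(w * v) / sum(w)
    mcSe <- sqrt(sum(w^2 * (v - mc)^2)) / sum(w)
    expect_lt(abs(posteriorMeanOracle(un, obs) - mc), 3 * mcSe + 1e-8)
  }
  # quadrature refinement changes the answer by < 1e-6
  un2 <- toyPosteriorModel("uniform", noiseSigma = 0.1, quadratureN = 4096L)
  expect_lt(max(abs(posteriorMeanOracle(un, c(0.1, 0.4, 0.9)) -
                    posteriorMeanOracle(un2, c(0.1, 0.4, 0.9)))), 1e-6)
})

test_that("cross-validation returns per-fold costs over the declared grid", {
  set.seed(47)
  truths <- lapply(1:20, function(i) matrix(runif(64), 8, 8))
  images <- lapply(truths, function(m) m + matrix(rnorm(64, 0, 0.1), 8, 8))
  grid <- data.frame(learningRate = c(1e-3, 3e-3), depth = 2,
                     baseChannels = 2)
  tc <- trainingConfig(epochs = 3, batchSize = 5, nFolds = 4, seed = 2)
  cv <- crossValidate(images, truths, grid, 8, tc)
  expect_equal(nrow(cv), 2)
  expect_true(all(is.finite(cv$meanValCost)))
  expect_identical(dim(attr(cv, "folds")), c(2L, 4L))
})
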