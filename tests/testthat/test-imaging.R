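test_that("forward projection is linear and zero maps to zero", {
  sys <- smallSystem()
  expect_true(all(values(forwardProject(matrix(0, 32, 32), sys)) == 0))
  set.seed(4)
  x <- matrix(runif(32^2), 32, 32); y <- matrix(runif(32^2), 32, 32)
  lhs <- values(forwardProject(2 * x + 3 * y, sys))
  rhs <- 2 * values(forwardProject(x, sys)) + 3 * values(forwardProject(y, sys))
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_error(forwardProject(matrix(0, 16, 16), sys), "match")
})

test_that("a point source traces the expected sinusoid within one bin", {
  sys <- systemModel(64, 4.07, 5, nAngles = 84)
  ps <- matrix(0, 64, 64); ps[40, 22] <- 1
  sn <- values(forwardProject(ps, sys))
  ctr <- (64 + 1) / 2
  yMm <- (40 - ctr) * 4.07; xMm <- (22 - ctr) * 4.07
  angles <- (seq_len(84) - 1) * pi / 84
  uExpected <- (xMm * cos(angles) + yMm * sin(angles)) / 4.07 + (64 + 1) / 2
  uObserved <- apply(sn, 1, which.max)
  expect_lt(max(abs(uObserved - uExpected)), 1)
})

test_that("back projection is the exact adjoint of forward projection", {
  sys <- smallSystem()
  set.seed(9)
  for (i in 1:5) {
    x <- matrix(runif(32^2), 32, 32)
    y <- matrix(runif(sys@nAngles * 32), sys@nAngles, 32)
    sino <- new("Sinogram", values = y, binSizeMm = 4.07, meta = list())
    lhs <- sum(values(forwardProject(x, sys)) * y)
    rhs <- sum(x * backProject(sino, sys))
    expect_lt(abs(lhs - rhs) / abs(rhs), 1e-6)
  }
})

test_that("high- and low-resolution projection paths agree on matched grids", {
  sys <- smallSystem()
  set.seed(2)
  ph <- samplePhantom(smallTumorConfig(), smallBackgroundParams(), 32, 4.07)
  sTum <- forwardProject(ph@tumorActivity, sys, highRes = TRUE)
  sBg <- forwardProject(ph@backgroundActivity, sys)
  comb <- combineSinograms(sTum, sBg)
  expect_equal(values(comb), values(sTum) + values(sBg))
  # at grid ratio 1 the high-res path is the low-res path exactly
  sys1 <- systemModel(32, 4.07, 5, nAngles = 42, gridRatio = 1L)
  x <- matrix(runif(32^2), 32, 32)
  expect_equal(values(forwardProject(x, sys1, highRes = TRUE)),
               values(forwardProject(x, sys1)), tolerance = 1e-12)
  # geometry mismatch is rejected
  bad <- new("Sinogram", values = matrix(0, 10, 10), binSizeMm = 1,
             meta = list())
  expect_error(combineSinograms(sTum, bad), "match")
})

test_that("poissonize matches Poisson moments and is seed-reproducible", {
  sys <- smallSystem(countScale = 1e5)
  sino <- forwardProject(diskMatrix(32, 6), sys)
  expect_error(poissonize(new("Sinogram",
                              values = matrix(0, sys@nAngles, 32),
                              binSizeMm = 4.07, meta = list()), sys),
               "empty")
  set.seed(5)
  draws <- replicate(100, sum(values(poissonize(sino, sys))))
  pooledSigma <- sqrt(sys@countScale / 100)
  expect_lt(abs(mean(draws) - sys@countScale), 3 * pooledSigma)
  # zero bins can never produce counts
  one <- withr::with_seed(8, values(poissonize(sino, sys)))
  expect_true(all(one[values(sino) == 0] == 0))
  two <- withr::with_seed(8, values(poissonize(sino, sys)))
  expect_identical(one, two)
})

test_that("MLEM increases the Poisson likelihood and approaches the phantom", {
  # near-ideal resolution so the reconstruction operator matches the data
  sys <- systemModel(32, 4.07, 0.01, nAngles = 48, countScale = 1e5)
  disk <- diskMatrix(32, 6)
  sino <- forwardProject(disk, sys)
  y <- as.numeric(t(values(sino)))
  f <- matrix(1, 32, 32)
  ll <- numeric(0); nrmse <- numeric(0)
  for (k in 1:15) {
    f <- values(osem(sino, sys, nSubsets = 1, nIterations = 1,
                     init = pmax(f, 1e-10)))
    lam <- as.numeric(sys@projector %*% as.numeric(f))
    ll <- c(ll, sum(y * log(pmax(lam, 1e-12)) - lam))
    nrmse <- c(nrmse, sqrt(mean((f - disk)^2)) / mean(disk))
  }
  expect_true(all(diff(ll) > -1e-6))
  expect_true(all(diff(nrmse) < 0))
})

test_that("MLEM likelihood is non-decreasing on random noisy sinograms", {
  sys <- smallSystem(countScale = 5e4)
  set.seed(14)
  for (rep in 1:10) {
    ph <- samplePhantom(smallTumorConfig(), smallBackgroundParams(), 32, 4.07)
    sino <- poissonize(combineSinograms(
      forwardProject(ph@tumorActivity, sys, highRes = TRUE),
      forwardProject(ph@backgroundActivity, sys)), sys)
    y <- as.numeric(t(values(sino)))
    f <- matrix(1, 32, 32); ll <- numeric(0)
    for (k in 1:5) {
      f <- values(osem(sino, sys, nSubsets = 1, nIterations = 1,
                       init = pmax(f, 1e-10)))
      lam <- as.numeric(sys@projector %*% as.numeric(f))
      ll <- c(ll, sum(y * log(pmax(lam, 1e-12)) - lam))
    }
    expect_true(all(diff(ll) > -1e-6))
  }
})

test_that("OSEM output is nonnegative, annihilates zero data, rejects bad init", {
  sys <- smallSystem()
  zero <- new("Sinogram", values = matrix(0, sys@nAngles, 32),
              binSizeMm = 4.07, meta = list())
  rec <- osem(zero, sys, nSubsets = 3, nIterations = 1)
  expect_true(all(values(rec) == 0))
  expect_error(osem(zero, sys, init = matrix(0, 32, 32)), "positive")
  sino <- forwardProject(diskMatrix(32, 6), sys)
  rec2 <- osem(sino, sys, nSubsets = 21, nIterations = 2)
  expect_true(all(values(rec2) >= 0))
})

test_that("reconstruction cannot beat the system resolution", {
  sys <- systemModel(64, 4.07, 5, nAngles = 84)
  ps <- matrix(0, 64, 64); ps[40, 22] <- 1
  rec <- values(osem(forwardProject(ps, sys), sys, 21, 2))
  expect_gte(momentFwhmMm(rec, 4.07), sys@fwhmMm)
})
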